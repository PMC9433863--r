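# pelvimarrow

Hematologic toxicity (HT) — leukopenia, neutropenia, anemia,
thrombocytopenia — is the dose-limiting side effect of concurrent
chemoradiotherapy for locally advanced cervical cancer, because the pelvis
and lower lumbar spine carry a large share of the body's active (red) bone
marrow. Baseline FDG-PET/CT can quantify how much of a patient's pelvic
marrow is metabolically active before treatment, and that quantity predicts
who will develop severe (grade 3+) cytopenias.

`pelvimarrow` implements this analysis as a tested R pipeline for imaging
researchers:

- **Active-marrow quantification.** Pelvic bone is segmented on CT as
  voxels with attenuation ≥ 150 HU inside an anatomical region of interest
  (L4–L5 down to the ischial tuberosity, supplied as a slab), with manual
  corrections expressed as explicit mask edits. Over the bone region
  `BM_TOT`, the patient's mean bone SUV is computed on the paired PET;
  the active marrow `BM_ACT` is the subregion with
  `SUV ≥ mean bone SUV`, and `BM_ACT% = 100 · BM_ACT / BM_TOT`. BM_ACT% is
  grouped as `<30%`, `30–40%`, `>40%` for the association analysis.
- **Tumor metabolic parameters.** From an ellipsoid VOI around the primary
  lesion: `SUVmax` (maximum SUV in the VOI), `MTV` (volume of VOI voxels
  with `SUV > 0.4 · SUVmax`) and `TLG = MTV · meanSUV(MTV)`, with optional
  clearing of interfering high-uptake structures (e.g. bladder) before
  measurement.
- **Toxicity grading.** Nadirs of WBC, ANC, HGB and PLT from weekly blood
  counts are graded against a configurable CTCAE-v5-style threshold table;
  the overall HT grade is the maximum component grade, split into G0–2 vs
  G3+.
- **Statistics.** The univariate battery (Kolmogorov–Smirnov/Lilliefors
  normality gate choosing pooled-variance t vs Mann–Whitney U with
  tie-corrected asymptotic Z; paired t vs Wilcoxon signed-rank; Pearson
  chi-square with automatic Yates correction for sparse 2×2 tables; Fisher
  exact; Holm–Bonferroni for the pairwise group comparisons), and binary
  logistic regression `logit P(G3+) = β₀ + βᵀx` with dummy-coded grouped
  BM_ACT% against the 30–40% reference, odds ratios `exp(β)` and Wald 95%
  intervals.
- **Synthetic data.** A phantom generator (annulus "pelvic bone" with a
  two-component marrow SUV model and a spherical-Gaussian lesion) with
  analytically known BM_ACT%, SUVmax and 40%-isocontour volume, and cohort
  generators reproducing the published marginal tables, so the whole
  pipeline is testable without patient data.

## Worked example

```r
library(pelvimarrow)

ph <- generate_phantom()                     # 3 mm PET/CT phantom
bone <- segment_bone(ph$ct, ph$roi, hu_threshold = 150)
compute_bm_metrics(ph$pet, bone)
#> <bm_metrics> BM_TOT 1254.53 cm3 | BM_ACT 439.07 cm3 | BM_ACT% 35.0% (MID30_40) | mean bone SUV 1.375
tumor_metrics(ph$pet, ph$voi, fraction = 0.40)
#> <tumor_metrics> SUVmax 17.50 | MTV 38.31 cm3 (>40% SUVmax) | TLG 402.2 | MTV mean SUV 10.50
```

The phantom's marrow was built with active fraction 0.35 and lesion peak
SUV 17.5, so the reported BM_ACT% (35.0, grouped into 30–40%) and SUVmax
(17.50) are exact recoveries; the MTV (38.31 cm³ at 3 mm spacing)
approaches the analytic 40%-isocontour volume 39.44 cm³ as the grid is
refined.

```r
co <- realize_table3_cohort()                # deterministic 41-patient cohort
build_table3(co$cohort)
#> Pairwise 2x2 comparisons:
#>        comparison     method statistic   p_raw p_holm
#>  LT30_vs_MID30_40       chi2    7.5380 0.00604 0.0181
#>  MID30_40_vs_GT40       chi2    3.8770 0.04900 0.0979
#>      LT30_vs_GT40 chi2_yates    0.3031 0.58200 0.5820
```

The fixture cohort's grouped BM_ACT% × HT cross-tab is [[10,3],[3,10],[9,6]];
the below-30% vs 30–40% comparison (χ² = 7.538, p = 0.006) and 30–40% vs
above-40% (χ² = 3.877, p = 0.049) differ, while below-30% vs above-40%
(Yates-corrected χ² = 0.303, p = 0.582) does not — the non-monotone
association that motivates treating BM_ACT% as grouped rather than linear.

A shell entry point over the same functions lives at
`inst/cli/pelvimarrow.R`:

```sh
Rscript inst/cli/pelvimarrow.R simulate --config run.yaml --seed 1 --out out/
Rscript inst/cli/pelvimarrow.R quant    --config run.yaml --out out/
Rscript inst/cli/pelvimarrow.R grade    --config run.yaml --out out/
Rscript inst/cli/pelvimarrow.R stats    --config run.yaml --out out/
```

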