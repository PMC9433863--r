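# Cytopenia grading thresholds in the style of CTCAE v5.
#
# For each analyte, `thresholds` lists four strictly decreasing upper
# bounds: a nadir strictly below thresholds[g] is at least grade g
# (g = 1..4), so grade = number of thresholds strictly greater than the
# value. A value exactly equal to a bound takes the milder grade (CTCAE
# phrases grade ranges as "< x"), and grade 0 means the value is at or
# above the grade-1 bound (the lower limit of normal).
#
# The grade-1 bound is the lower limit of normal (LLN); CTCAE defines
# grade 1 relative to the institutional LLN, so the values here (and the
# operational anemia grade-4 bound, which CTCAE v5 leaves descriptive as
# "life-threatening") are editable site defaults, not universal constants.
version: "ctcae-v5-defaults-1"
boundary: milder-at-equality
analytes:
  wbc:
    name: leukopenia
    unit: 1e9/L
    thresholds: [4.0, 3.0, 2.0, 1.0]
  anc:
    name: neutropenia
    unit: 1e9/L
    thresholds: [2.0, 1.5, 1.0, 0.5]
  hgb:
    name: anemia
    unit: g/L
    thresholds: [115, 100, 80, 65]
  plt:
    name: thrombocytopenia
    unit: 1e9/L
    thresholds: [125, 75, 50, 25]
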