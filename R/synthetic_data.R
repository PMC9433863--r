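#' Phantom configuration
#'
#' Parameters for the PET/CT software phantom: a cylindrical-annulus
#' "pelvic bone" in a soft-tissue background, a two-component marrow SUV
#' model inside the bone (a fraction `active_fraction` of bone voxels at
#' `suv_hi`, the rest at `suv_lo`, so the recovered BM_ACT% is known by
#' construction), a spherical-Gaussian primary lesion whose SUVmax and
#' 40% isocontour volume are analytic, and an optional hot "bladder"
#' sphere for interference-clearing tests. The default lesion matches a
#' reported clinical case (peak SUV 17.5; sigma chosen so the analytic
#' 40% isocontour volume is 39.4 cm3).
#'
#' @param spacing Voxel spacing, mm (default 3 mm isotropic, the
#'   acquisition slice thickness emulated).
#' @param extent Physical grid extent, mm.
#' @param body_hu,bone_hu Soft-tissue and bone attenuation (HU).
#' @param background_suv Soft-tissue SUV.
#' @param bone List: `outer_r`, `inner_r` (annulus radii, mm), `z`
#'   (axial extent, mm).
#' @param marrow List: `active_fraction` in (0,1), `suv_hi > suv_lo >= 0`.
#' @param lesion List: `sigma` (mm), `peak` (SUV).
#' @param bladder `NULL` or list `center` (mm), `radius` (mm), `suv`.
#' @param seed Integer seed controlling which bone voxels are active.
#' @return List of class `phantom_config`.
#' @export
phantom_config <- function(spacing = c(3, 3, 3),
                           extent = c(192, 192, 192),
                           body_hu = 40, bone_hu = 700,
                           background_suv = 0.5,
                           bone = list(outer_r = 85, inner_r = 65,
                                       z = c(30, 160)),
                           marrow = list(active_fraction = 0.35,
                                         suv_hi = 3.0, suv_lo = 0.5),
                           lesion = list(sigma = 15.599, peak = 17.5),
                           bladder = NULL,
                           seed = 1L) {
  f <- marrow$active_fraction
  if (!(f > 0 && f < 1)) stop("active_fraction must be in (0, 1)")
  if (!(marrow$suv_hi > marrow$suv_lo && marrow$suv_lo >= 0))
    stop("need suv_hi > suv_lo >= 0")
  if (lesion$peak <= background_suv)
    stop("lesion peak must exceed the background SUV")
  if (bone$inner_r >= bone$outer_r) stop("need inner_r < outer_r")
  if (bone$outer_r * 2 > min(extent[1:2]) || bone$z[2] > extent[3])
    stop("bone geometry does not fit inside the grid")
  structure(list(spacing = as.numeric(spacing), extent = as.numeric(extent),
                 body_hu = body_hu, bone_hu = bone_hu,
                 background_suv = background_suv, bone = bone,
                 marrow = marrow, lesion = lesion, bladder = bladder,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Generate a PET/CT phantom with known ground truth
#'
#' Deterministic given the config seed. The truth record carries the
#' exact bone voxel count, the realized active fraction (the requested
#' fraction quantized to a whole number of voxels), the analytic lesion
#' SUVmax (the lesion center coincides with a voxel center) and the
#' analytic 40% isocontour volume.
#'
#' @param cfg A [phantom_config()].
#' @return List with `ct` and `pet` [image_volume()]s, `roi`
#'   ([pelvic_roi()] covering the bone slab), `voi` ([ellipsoid_voi()]
#'   enclosing the lesion), and `truth` (list with `n_bone`, `n_active`,
#'   `bm_act_pct`, `active_fraction`, `suvmax`, `mtv_analytic_cm3`,
#'   `lesion_center_mm`).
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  sp <- cfg$spacing
  shape <- as.integer(round(cfg$extent / sp))
  coords <- lapply(1:3, function(ax) (seq_len(shape[ax]) - 1) * sp[ax])
  # lesion / bone axis center snapped to a voxel center
  cidx <- floor(shape / 2) + 1L
  cmm <- vapply(1:3, function(ax) coords[[ax]][cidx[ax]], numeric(1))

  dx2 <- (coords[[1]] - cmm[1])^2
  dy2 <- (coords[[2]] - cmm[2])^2
  r2_xy <- outer(dx2, dy2, "+")                      # in-plane radius^2
  z <- coords[[3]]
  in_slab <- z >= cfg$bone$z[1] & z <= cfg$bone$z[2]
  ring <- r2_xy >= cfg$bone$inner_r^2 & r2_xy <= cfg$bone$outer_r^2
  bone <- array(FALSE, shape)
  bone[, , which(in_slab)] <- ring                    # recycled per slice

  ct <- array(cfg$body_hu, shape)
  ct[bone] <- cfg$bone_hu

  pet <- array(cfg$background_suv, shape)
  n_bone <- sum(bone)
  n_active <- as.integer(round(cfg$marrow$active_fraction * n_bone))
  marrow_vals <- rep(cfg$marrow$suv_lo, n_bone)
  set.seed(cfg$seed)
  marrow_vals[sample.int(n_bone, n_active)] <- cfg$marrow$suv_hi
  pet[bone] <- marrow_vals

  dz2 <- (z - cmm[3])^2
  r2 <- outer(r2_xy, dz2, "+")
  gauss <- cfg$lesion$peak * exp(-r2 / (2 * cfg$lesion$sigma^2))
  soft <- !bone
  pet[soft] <- pmax(pet[soft], gauss[soft])

  if (!is.null(cfg$bladder)) {
    b <- cfg$bladder
    bx2 <- (coords[[1]] - b$center[1])^2
    by2 <- (coords[[2]] - b$center[2])^2
    bz2 <- (coords[[3]] - b$center[3])^2
    bl <- outer(outer(bx2, by2, "+"), bz2, "+") <= b$radius^2
    pet[bl & !bone] <- b$suv
  }

  k_in <- which(in_slab)
  voi_r <- cfg$lesion$sigma * sqrt(2 * log(cfg$lesion$peak /
                                           cfg$background_suv)) + 3 * max(sp)
  truth <- list(
    n_bone = n_bone, n_active = n_active,
    bm_act_pct = 100 * n_active / n_bone,
    active_fraction = n_active / n_bone,
    requested_fraction = cfg$marrow$active_fraction,
    suvmax = cfg$lesion$peak,
    mtv_analytic_cm3 = gaussian_isocontour_cm3(cfg$lesion$sigma, 0.40),
    lesion_center_mm = cmm)
  list(ct = image_volume(ct, sp, "CT"),
       pet = image_volume(pet, sp, "PET"),
       roi = pelvic_roi(min(k_in), max(k_in)),
       voi = ellipsoid_voi(cmm, rep(voi_r, 3)),
       truth = truth)
}

#' Cohort configuration
#'
#' Generator parameters for synthetic clinical cohorts. The defaults are
#' the study conditions of the emulated cohort: n = 41; age 52.6 +/- 10.4
#' and BMI 22.6 +/- 3.0; FIGO stage probabilities 6/32/3 out of 41 and
#' differentiation 7/24/10; baseline blood counts WBC 7.27 +/- 3.91,
#' ANC 5.12 +/- 3.60 (1e9/L), HGB 133 +/- 10 (g/L), PLT 248 +/- 73
#' (1e9/L), truncated at the lower limit of normal (no pre-treatment
#' cytopenia); BM_ACT% group probabilities 13/41, 13/41, 15/41 with
#' group-conditional grade 3+ probabilities 3/13, 10/13, 6/15.
#'
#' @param n Number of patients.
#' @param seed Integer seed.
#' @param group_probs Probabilities of the three BM_ACT% groups (LT30,
#'   MID30_40, GT40), summing to 1.
#' @param g3_prob_by_group Conditional probability of grade 3+ HT per
#'   group, same order.
#' @param grade_probs_g02,grade_probs_g3 Conditional distribution of the
#'   overall grade within the grade 0-2 stratum (grades 0,1,2) and the
#'   grade 3+ stratum (grades 3,4); defaults from the emulated grade
#'   table (2,2,18 / 15,4).
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n = 41L, seed = 1L,
                          group_probs = c(13, 13, 15) / 41,
                          g3_prob_by_group = c(3 / 13, 10 / 13, 6 / 15),
                          grade_probs_g02 = c(2, 2, 18) / 22,
                          grade_probs_g3 = c(15, 4) / 19) {
  if (abs(sum(group_probs) - 1) > 1e-9) stop("group_probs must sum to 1")
  if (any(g3_prob_by_group < 0 | g3_prob_by_group > 1))
    stop("g3_prob_by_group must be probabilities")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 group_probs = group_probs,
                 g3_prob_by_group = g3_prob_by_group,
                 grade_probs_g02 = grade_probs_g02 / sum(grade_probs_g02),
                 grade_probs_g3 = grade_probs_g3 / sum(grade_probs_g3)),
            class = "cohort_config")
}

# analyte order and generator constants
.blood_base <- list(
  mean = c(wbc = 7.27, anc = 5.12, hgb = 133, plt = 248),
  sd = c(wbc = 3.91, anc = 3.60, hgb = 10, plt = 73))
.driver_probs <- c(wbc = 0.40, anc = 0.30, hgb = 0.15, plt = 0.15)
.co_grade_prob <- c(wbc = 0.55, anc = 0.50, hgb = 0.40, plt = 0.35)
.series_days <- c(0, 7, 14, 21, 28, 35)

# truncated normal via inverse CDF
rtnorm_lo <- function(n, mean, sd, lo) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

# nadir sampling interval for a target grade (see grade_table semantics);
# grade 0 nadir lies between the LLN and the baseline
grade_interval <- function(analyte, grade, table, baseline) {
  th <- table$thresholds[[analyte]]
  if (grade == 0) c(th[1], max(baseline, th[1] * 1.001))
  else if (grade < 4) c(th[grade + 1], th[grade])
  else c(0.3 * th[4], th[4])
}

sample_in <- function(iv) stats::runif(1, iv[1] + 0.01 * diff(iv),
                                       iv[2] - 0.01 * diff(iv))

# weekly series declining linearly from baseline to the nadir (day 28)
# with partial recovery at day 35; the minimum is exactly the nadir
build_series_values <- function(baseline, nadir_val) {
  w <- c(0, 0.25, 0.55, 0.8, 1, 0.7)
  baseline + w * (nadir_val - baseline)
}

#' Generate a synthetic clinical cohort
#'
#' Draws, per patient: a BM_ACT% group and a uniform BM_ACT% inside the
#' group's interval (truncated to \[5, 70\] overall); a grade 3+
#' indicator from the group-conditional probability; an overall HT grade
#' from the within-stratum grade distribution; per-analyte cytopenia
#' grades (a randomly chosen driver analyte carries the overall grade,
#' the others are binomially attenuated below it); covariates drawn
#' independently of outcome; and a weekly blood-count series constructed
#' backwards from the target grades, with each nadir sampled strictly
#' inside the matching grade interval of the threshold table, so that
#' re-grading the series reproduces the drawn grades with probability 1.
#'
#' @param cfg A [cohort_config()].
#' @param table Grade-threshold table used to invert grades into nadir
#'   intervals (default the packaged table).
#' @return List with `cohort` (one row per patient: covariates, marrow
#'   and tumor metrics, HT columns from actually re-grading the series)
#'   and `blood` (stacked per-patient series: `patient_id`, `day`, `wbc`,
#'   `anc`, `hgb`, `plt`). The drawn (intended) grades are attached as
#'   `attr(cohort, "intended_grades")`.
#' @export
generate_cohort <- function(cfg = cohort_config(),
                            table = default_grade_table()) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  n <- cfg$n
  groups <- sample(bm_group_levels(), n, replace = TRUE,
                   prob = cfg$group_probs)
  pct_range <- list(LT30 = c(5, 30), MID30_40 = c(30, 40),
                    GT40 = c(40, 70))
  bm_act_pct <- vapply(groups, function(g) sample_in(pct_range[[g]]),
                       numeric(1))
  p_g3 <- cfg$g3_prob_by_group[match(groups, bm_group_levels())]
  is_g3 <- stats::rbinom(n, 1, p_g3) == 1
  overall <- integer(n)
  overall[is_g3] <- sample(3:4, sum(is_g3), replace = TRUE,
                           prob = cfg$grade_probs_g3)
  overall[!is_g3] <- sample(0:2, sum(!is_g3), replace = TRUE,
                            prob = cfg$grade_probs_g02)

  analytes <- ht_analytes()
  grades <- matrix(0L, n, 4, dimnames = list(NULL, analytes))
  for (i in seq_len(n)) {
    drv <- sample(analytes, 1, prob = .driver_probs)
    for (an in analytes) {
      grades[i, an] <- if (an == drv) overall[i]
      else stats::rbinom(1, overall[i], .co_grade_prob[an])
    }
  }

  baselines <- sapply(analytes, function(an)
    rtnorm_lo(n, .blood_base$mean[an], .blood_base$sd[an],
              table$thresholds[[an]][1] * 1.02))
  blood <- vector("list", n)
  for (i in seq_len(n)) {
    vals <- sapply(analytes, function(an) {
      iv <- grade_interval(an, grades[i, an], table, baselines[i, an])
      build_series_values(baselines[i, an], sample_in(iv))
    })
    blood[[i]] <- data.frame(patient_id = i, day = .series_days, vals)
  }
  blood <- do.call(rbind, blood)

  bm_tot <- rtnorm_lo(n, 410, 90, 150)
  suvmax <- pmax(2, stats::rlnorm(n, meanlog = 2.65, sdlog = 0.5))
  mtv <- pmax(1, stats::rgamma(n, shape = 1.61, scale = 35.5 / 1.61))
  cohort <- data.frame(
    patient_id = seq_len(n),
    age = stats::rnorm(n, 52.6, 10.4),
    bmi = stats::rnorm(n, 22.6, 3.0),
    figo = sample(c("IB2_II", "III", "IVA"), n, replace = TRUE,
                  prob = c(6, 32, 3) / 41),
    differentiation = sample(c("low", "middle", "high"), n, replace = TRUE,
                             prob = c(7, 24, 10) / 41),
    max_diameter = pmax(1, stats::rnorm(n, 5.04, 1.66)),
    parametrial_invasion = ifelse(stats::rbinom(n, 1, 29 / 41) == 1,
                                  "yes", "no"),
    ln_metastasis = ifelse(stats::rbinom(n, 1, 29 / 41) == 1, "yes", "no"),
    bm_tot_cm3 = bm_tot,
    bm_act_cm3 = bm_act_pct / 100 * bm_tot,
    bm_act_pct = bm_act_pct,
    bm_group = groups,
    suvmax = suvmax,
    mtv_cm3 = mtv,
    tlg = mtv * pmax(1.5, 0.55 * suvmax),
    stringsAsFactors = FALSE)
  ht <- ht_table(blood, table)
  cohort <- merge(cohort, ht, by = "patient_id", sort = TRUE)
  cohort <- cohort[order(cohort$patient_id), ]
  rownames(cohort) <- NULL
  attr(cohort, "intended_grades") <-
    cbind(as.data.frame(grades), overall = overall)
  list(cohort = cohort, blood = blood)
}

# deterministic bijective scramble of 1..n used to decorrelate fixture
# covariates from the outcome-ordered patient list
.scramble <- function(n, a) order((seq_len(n) * a) %% n)

#' Deterministic 41-patient fixture cohort
#'
#' A fully deterministic cohort (no RNG) whose grouped BM_ACT% x HT-group
#' cross-tabulation is exactly \[\[10,3\],\[3,10\],\[9,6\]\] and whose
#' per-analyte cytopenia grade distributions reproduce the emulated
#' toxicity table exactly (overall 2,2,18,15,4 across grades 0-4;
#' leukopenia 3,7,17,13,1; neutropenia 14,6,8,10,3; anemia 14,7,16,4,0;
#' thrombocytopenia 21,7,10,1,2), with the overall grade equal to the
#' per-patient maximum component grade. Blood series are constructed so
#' that grading them reproduces these grades; covariates follow the
#' cohort's marginal distributions via deterministic quantile spreads,
#' scrambled so they carry no outcome signal.
#'
#' @param table Grade-threshold table used to invert grades into nadirs.
#' @return List with `cohort` and `blood` as in [generate_cohort()].
#' @export
realize_table3_cohort <- function(table = default_grade_table()) {
  # per-overall-grade strata: G0-2 first (grades 0,0,1,1,2 x 18), then
  # G3+ (3 x 15, 4 x 4); analyte grades solved so all row multisets of
  # the toxicity table are met and max(row) == overall for every patient
  overall <- c(rep(0L, 2), rep(1L, 2), rep(2L, 18), rep(3L, 15), rep(4L, 4))
  leuko <- c(0, 0, 1, 1,
             rep(2, 12), rep(1, 5), 0,
             rep(3, 13), 2, 2,
             4, 2, 2, 2)
  neutro <- c(0, 0, 1, 1,
              rep(0, 8), rep(1, 3), 2, rep(2, 6),
              rep(3, 8), 2, 1, rep(0, 3), 3, 3,
              0, 4, 4, 4)
  anemia <- c(0, 0, 1, 1,
              rep(0, 6), rep(1, 3), rep(2, 9),
              rep(3, 4), rep(2, 6), rep(1, 2), rep(0, 3),
              0, 0, 0, 2)
  thrombo <- c(0, 0, 0, 1,
               rep(0, 12), rep(1, 4), 2, 2,
               3, rep(2, 7), rep(1, 2), rep(0, 5),
               4, 4, 2, 0)
  grades <- cbind(wbc = as.integer(leuko), anc = as.integer(neutro),
                  hgb = as.integer(anemia), plt = as.integer(thrombo))
  stopifnot(apply(grades, 1, max) == overall)
  n <- length(overall)

  # BM_ACT% groups: 10/3/9 among G0-2 (first 22), 3/10/6 among G3+
  groups <- c(rep("LT30", 10), rep("MID30_40", 3), rep("GT40", 9),
              rep("LT30", 3), rep("MID30_40", 10), rep("GT40", 6))
  bm_act_pct <- numeric(n)
  for (g in bm_group_levels()) {
    idx <- which(groups == g)
    rng <- switch(g, LT30 = c(10, 29), MID30_40 = c(30.5, 39.5),
                  GT40 = c(40.5, 58))
    bm_act_pct[idx] <- seq(rng[1], rng[2], length.out = length(idx))
  }

  analytes <- ht_analytes()
  base_jit <- list(wbc = 1.2, anc = 1.0, hgb = 5, plt = 35)
  blood <- vector("list", n)
  for (i in seq_len(n)) {
    vals <- sapply(analytes, function(an) {
      b <- .blood_base$mean[[an]] + base_jit[[an]] * sin(i)
      g <- grades[i, an]
      iv <- grade_interval(an, g, table, b)
      build_series_values(b, mean(iv))
    })
    blood[[i]] <- data.frame(patient_id = i, day = .series_days, vals)
  }
  blood <- do.call(rbind, blood)

  qspread <- function(mean, sd, a, lo = -Inf) {
    v <- stats::qnorm((seq_len(n) - 0.5) / n) * sd + mean
    pmax(lo, v)[.scramble(n, a)]
  }
  cat_spread <- function(levels, counts, a)
    rep(levels, counts)[.scramble(n, a)]

  bm_tot <- qspread(410, 90, 7, lo = 150)
  suvmax <- exp(qspread(2.65, 0.5, 11))
  mtv <- pmax(1, qspread(35.5, 28, 31))
  cohort <- data.frame(
    patient_id = seq_len(n),
    age = qspread(52.6, 10.4, 17),
    bmi = qspread(22.6, 3.0, 3, lo = 15),
    figo = cat_spread(c("IB2_II", "III", "IVA"), c(6, 32, 3), 13),
    differentiation = cat_spread(c("low", "middle", "high"),
                                 c(7, 24, 10), 19),
    max_diameter = qspread(5.04, 1.66, 23, lo = 1),
    parametrial_invasion = cat_spread(c("yes", "no"), c(29, 12), 29),
    ln_metastasis = cat_spread(c("yes", "no"), c(29, 12), 37),
    bm_tot_cm3 = bm_tot,
    bm_act_cm3 = bm_act_pct / 100 * bm_tot,
    bm_act_pct = bm_act_pct,
    bm_group = groups,
    suvmax = suvmax,
    mtv_cm3 = mtv,
    tlg = mtv * pmax(1.5, 0.55 * suvmax),
    stringsAsFactors = FALSE)
  ht <- ht_table(blood, table)
  cohort <- merge(cohort, ht, by = "patient_id", sort = TRUE)
  cohort <- cohort[order(cohort$patient_id), ]
  rownames(cohort) <- NULL
  attr(cohort, "intended_grades") <-
    cbind(as.data.frame(grades), overall = overall)
  list(cohort = cohort, blood = blood)
}

#' Simulate a cohort from a known logistic model
#'
#' For parameter-recovery checks: draws SUVmax (lognormal) and a BM_ACT%
#' group (probabilities 13/13/15 out of 41), then a binary outcome from
#' `logit p = beta0 + beta_suv * suvmax + beta_lt30 * [LT30] +
#' beta_gt40 * [GT40]` with the 30%-40% group as reference.
#'
#' @param n Cohort size.
#' @param beta0,beta_suv,beta_lt30,beta_gt40 True log-odds parameters.
#' @param seed Integer seed.
#' @return Data frame with `suvmax`, `bm_group` and binary `ht`.
#' @export
simulate_logistic_cohort <- function(n, beta0 = -1, beta_suv = 0.1,
                                     beta_lt30 = 1, beta_gt40 = -1,
                                     seed = 1L) {
  set.seed(seed)
  suvmax <- stats::rlnorm(n, 2.65, 0.5)
  grp <- sample(bm_group_levels(), n, replace = TRUE,
                prob = c(13, 13, 15) / 41)
  eta <- beta0 + beta_suv * suvmax +
    beta_lt30 * (grp == "LT30") + beta_gt40 * (grp == "GT40")
  data.frame(suvmax = suvmax, bm_group = grp,
             ht = stats::rbinom(n, 1, stats::plogis(eta)))
}
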