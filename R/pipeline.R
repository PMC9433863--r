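#' Read a pipeline run configuration
#'
#' YAML configuration shared by the `cmd_*` stages. Recognised keys:
#' `seed`, `out_dir`, `thresholds` (`hu_bone`, `mtv_fraction`),
#' `grading_table` (path; `NULL` for the packaged defaults), `phantom`
#' and `cohort` (generator overrides for [cmd_simulate()]), `patients`
#' (list of per-patient records for [cmd_quant()]: `id`, `ct`, `pet`,
#' `roi: {z_lo, z_hi}`, `voi: {center_mm, radii_mm}`, optional
#' `mask_edits` CSV and `interference` NIfTI), `blood` (CSV path for
#' [cmd_grade()]) and `cohort_csv` (for [cmd_stats()]).
#'
#' @param path YAML file.
#' @return Named list of class `run_config` (with the config file path
#'   attached for provenance).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$config_path <- path
  structure(cfg, class = "run_config")
}

# provenance record written next to each stage's outputs
write_provenance <- function(cfg, out_dir, stage) {
  rec <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("pelvimarrow")),
    seed = cfg$seed %||% NA,
    config_md5 = if (!is.null(cfg$config_path) && file.exists(cfg$config_path))
      unname(tools::md5sum(cfg$config_path)) else NA)
  jsonlite::write_json(rec, file.path(out_dir,
                                      paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Simulate a fixture tree
#'
#' Writes a PET/CT phantom (NIfTI volumes + ground-truth JSON) and a
#' synthetic cohort (cohort CSV + stacked blood-series CSV) under the
#' configured output directory. Deterministic given the seed.
#'
#' @param cfg A [read_run_config()] result or compatible list; uses
#'   `cfg$out_dir`, `cfg$seed`, and optional `cfg$phantom` / `cfg$cohort`
#'   generator overrides.
#' @return Invisibly, the list of written paths.
#' @export
cmd_simulate <- function(cfg) {
  out <- cfg$out_dir %||% "."
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)

  pargs <- cfg$phantom %||% list()
  pargs$seed <- seed
  ph <- generate_phantom(do.call(phantom_config, pargs))
  write_volume(ph$ct, file.path(out, "phantom_ct.nii.gz"))
  write_volume(ph$pet, file.path(out, "phantom_pet.nii.gz"))
  truth <- ph$truth
  truth$roi <- list(z_lo = ph$roi$z_lo, z_hi = ph$roi$z_hi)
  truth$voi <- list(center_mm = ph$voi$center, radii_mm = ph$voi$radii)
  jsonlite::write_json(truth, file.path(out, "phantom_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cargs <- cfg$cohort %||% list()
  cargs$seed <- seed
  co <- generate_cohort(do.call(cohort_config, cargs))
  utils::write.csv(co$cohort, file.path(out, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(co$blood, file.path(out, "blood.csv"),
                   row.names = FALSE)
  write_provenance(cfg, out, "simulate")
  invisible(file.path(out, c("phantom_ct.nii.gz", "phantom_pet.nii.gz",
                             "phantom_truth.json", "cohort.csv",
                             "blood.csv")))
}

# quantify one patient record; errors propagate to the caller
quant_one <- function(p, thresholds, out_dir) {
  ct <- read_volume(p$ct, "CT")
  pet <- read_volume(p$pet, "PET")
  check_paired_grid(ct, pet)
  roi <- pelvic_roi(p$roi$z_lo, p$roi$z_hi)
  bone <- segment_bone(ct, roi, thresholds$hu_bone %||% 150)
  n_edits <- 0L
  if (!is.null(p$mask_edits)) {
    ed <- read_mask_edits(p$mask_edits)
    n_edits <- nrow(ed)
    bone <- apply_mask_edits(bone, ed)
  }
  bm <- compute_bm_metrics(pet, bone)
  voi <- ellipsoid_voi(p$voi$center_mm, p$voi$radii_mm)
  interf <- if (!is.null(p$interference)) read_mask(p$interference)
  tm <- tumor_metrics(pet, voi, thresholds$mtv_fraction %||% 0.40,
                      interference = interf)
  data.frame(patient_id = p$id,
             bm_tot_cm3 = bm$bm_tot_cm3, bm_act_cm3 = bm$bm_act_cm3,
             bm_act_pct = bm$bm_act_pct, bone_mean_suv = bm$bone_mean_suv,
             bm_group = bm$bm_group,
             suvmax = tm$suvmax, mtv_cm3 = tm$mtv_cm3, tlg = tm$tlg,
             mtv_fraction = tm$threshold_fraction,
             n_mask_edits = n_edits, stringsAsFactors = FALSE)
}

#' Quantify marrow and tumor metrics for configured patients
#'
#' Chains bone segmentation, mask correction, BM metrics and tumor
#' metrics for every patient record in the config. Per-patient failures
#' are collected (and reported in the return value) rather than aborting
#' the run; successful rows are still written.
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, a list with `metrics` (data frame) and `failures`
#'   (named character vector of error messages, empty if all succeeded).
#' @export
cmd_quant <- function(cfg) {
  out <- cfg$out_dir %||% "."
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  thresholds <- cfg$thresholds %||% list()
  rows <- list(); failures <- character(0)
  for (p in cfg$patients) {
    r <- tryCatch(quant_one(p, thresholds, out), error = function(e) e)
    if (inherits(r, "error")) {
      failures[as.character(p$id)] <- conditionMessage(r)
      message("patient ", p$id, " failed: ", conditionMessage(r))
    } else rows[[length(rows) + 1L]] <- r
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(metrics))
    utils::write.csv(metrics, file.path(out, "metrics.csv"),
                     row.names = FALSE)
  write_provenance(cfg, out, "quant")
  invisible(list(metrics = metrics, failures = failures))
}

#' Grade blood-count series for a cohort
#'
#' Reads the stacked blood-series CSV, grades every patient and writes
#' the per-patient toxicity table plus a grade-distribution summary.
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, a list with `ht` (per-patient data frame) and
#'   `distribution` (toxicity x grade count matrix).
#' @export
cmd_grade <- function(cfg) {
  out <- cfg$out_dir %||% "."
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  blood_path <- cfg$blood %||% file.path(out, "blood.csv")
  blood <- utils::read.csv(blood_path, stringsAsFactors = FALSE)
  table <- if (!is.null(cfg$grading_table))
    read_grade_table(cfg$grading_table) else default_grade_table()
  if (nrow(blood) == 0L) {
    ht <- data.frame(patient_id = integer(), g_leuko = integer(),
                     g_neutro = integer(), g_anemia = integer(),
                     g_thrombo = integer(), ht_grade = integer(),
                     ht_group = character())
  } else ht <- ht_table(blood, table)
  utils::write.csv(ht, file.path(out, "ht.csv"), row.names = FALSE)
  dist <- ht_grade_distribution(ht)
  utils::write.csv(cbind(toxicity = rownames(dist), as.data.frame(dist)),
                   file.path(out, "ht_summary.csv"), row.names = FALSE)
  write_provenance(cfg, out, "grade")
  invisible(list(ht = ht, distribution = dist))
}

#' Run the statistical battery on a cohort table
#'
#' Runs [build_table3()] on the cohort CSV (merged with the graded
#' toxicity table if `ht.csv` is present in the output directory and the
#' cohort lacks HT columns), writes tidy CSVs of the univariate,
#' pairwise and logistic results, and fits the logistic model on the
#' variables passing the univariate screen (grouped BM_ACT% uses the
#' 30%-40% reference).
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, a list with `table3` ([build_table3()] result) and
#'   `logistic` ([logistic_fit()] result, or `NULL` if no variable passed
#'   the screen).
#' @export
cmd_stats <- function(cfg) {
  out <- cfg$out_dir %||% "."
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cohort_path <- cfg$cohort_csv %||% file.path(out, "cohort.csv")
  cohort <- utils::read.csv(cohort_path, stringsAsFactors = FALSE)
  if (!"ht_group" %in% names(cohort)) {
    ht_path <- file.path(out, "ht.csv")
    if (!file.exists(ht_path))
      stop("cohort has no ht_group column and no ht.csv is available")
    cohort <- merge(cohort, utils::read.csv(ht_path), by = "patient_id")
  }
  t3 <- build_table3(cohort, cfg$stats$screen_p %||% 0.1)
  utils::write.csv(t3$univariate, file.path(out, "univariate.csv"),
                   row.names = FALSE)
  utils::write.csv(t3$pairwise, file.path(out, "pairwise.csv"),
                   row.names = FALSE)

  model_vars <- intersect(t3$screened,
                          c(table3_continuous(), "bm_group"))
  model_vars <- setdiff(model_vars, "bm_act_pct")  # grouped form is used
  logistic <- NULL
  if (length(model_vars)) {
    cohort$ht <- as.integer(cohort$ht_group == "G3plus")
    fml <- stats::reformulate(model_vars, response = "ht")
    ref <- if ("bm_group" %in% model_vars) list(bm_group = "MID30_40")
    logistic <- logistic_fit(fml, cohort, ref_levels = ref)
    if (logistic$separation)
      warning("possible separation in the logistic fit")
    utils::write.csv(logistic$terms, file.path(out, "logistic.csv"),
                     row.names = FALSE)
  }
  write_provenance(cfg, out, "stats")
  invisible(list(table3 = t3, logistic = logistic))
}

#' Run simulate, quant-free grading and stats end to end
#'
#' Convenience wrapper: [cmd_simulate()], then [cmd_grade()] and
#' [cmd_stats()] on the simulated outputs.
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, the [cmd_stats()] result.
#' @export
cmd_all <- function(cfg) {
  cmd_simulate(cfg)
  cmd_grade(cfg)
  invisible(cmd_stats(cfg))
}
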