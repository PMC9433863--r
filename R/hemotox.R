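#' Analytes graded by the toxicity module
#' @keywords internal
ht_analytes <- function() c("wbc", "anc", "hgb", "plt")

# toxicity name per analyte, fixed order
ht_toxicities <- function()
  c(wbc = "leukopenia", anc = "neutropenia",
    hgb = "anemia", plt = "thrombocytopenia")

#' Read a cytopenia grade-threshold table
#'
#' The table gives, per analyte (`wbc`, `anc`, `hgb`, `plt`), four
#' strictly decreasing upper bounds: a value strictly below bound `g` is
#' at least grade `g`. A value exactly equal to a bound takes the milder
#' grade; values at or above the grade-1 bound (lower limit of normal)
#' are grade 0. The numeric bounds ship as an editable YAML config
#' ([default_grade_table()] loads the packaged CTCAE v5 style defaults).
#'
#' @param path YAML file keyed by analyte with a `thresholds` list.
#' @return Object of class `grade_table`: a named list of decreasing
#'   numeric threshold vectors plus the config metadata.
#' @export
read_grade_table <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$analytes)) stop("grade table must have an `analytes` key")
  th <- lapply(cfg$analytes, function(a) as.numeric(a$thresholds))
  for (an in ht_analytes()) {
    if (is.null(th[[an]]))
      stop("grade table is missing analyte: ", an)
    if (length(th[[an]]) != 4L || any(diff(th[[an]]) >= 0))
      stop("thresholds for ", an, " must be 4 strictly decreasing values")
  }
  structure(list(thresholds = th[ht_analytes()],
                 version = cfg$version %||% "unversioned"),
            class = "grade_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_grade_table
#' @export
default_grade_table <- function() {
  read_grade_table(system.file("extdata", "ctcae_v5.yaml",
                               package = "pelvimarrow", mustWork = TRUE))
}

#' Validate a per-patient blood-count series
#'
#' A series is a data frame with one row per timepoint, ordered by `day`,
#' whose first row is the pre-treatment baseline, with nonnegative columns
#' `wbc`, `anc` (1e9/L), `hgb` (g/L) and `plt` (1e9/L). At least two
#' timepoints (baseline + one on-treatment) are required. Extra counts
#' (e.g. after transfusion) are simply additional rows.
#'
#' @param series Data frame as above (a `day` column is optional but, if
#'   present, must be nondecreasing).
#' @return The series, invisibly; errors on violation.
#' @export
validate_blood_series <- function(series) {
  stopifnot(is.data.frame(series))
  if (nrow(series) < 2L)
    stop("need at least baseline + one on-treatment timepoint")
  present <- intersect(ht_analytes(), names(series))
  if (length(present) == 0L) stop("no analyte columns found")
  for (an in present) {
    v <- series[[an]]
    if (any(v[!is.na(v)] < 0)) stop("negative counts for ", an)
  }
  if (!is.null(series$day) && is.unsorted(series$day))
    stop("timepoints must be ordered by day")
  invisible(series)
}

#' Nadir of a blood-count series
#'
#' Minimum recorded value for one analyte. The baseline is included by
#' default: the worst value over the whole series is graded, and for
#' patients without pre-treatment cytopenia the baseline never attains
#' the minimum anyway.
#'
#' @param series Blood series data frame (see [validate_blood_series()]).
#' @param analyte One of `"wbc"`, `"anc"`, `"hgb"`, `"plt"`.
#' @param include_baseline Include the first row? Default `TRUE`.
#' @return The nadir value.
#' @export
nadir <- function(series, analyte, include_baseline = TRUE) {
  analyte <- match.arg(analyte, ht_analytes())
  validate_blood_series(series)
  v <- series[[analyte]]
  if (is.null(v)) stop("analyte column missing: ", analyte)
  if (!include_baseline) v <- v[-1]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("analyte ", analyte, " missing at all timepoints")
  min(v)
}

#' Grade a blood-count value
#'
#' @param value Nonnegative count (vectorized).
#' @param analyte One of `"wbc"`, `"anc"`, `"hgb"`, `"plt"`.
#' @param table A [read_grade_table()] result; defaults to the packaged
#'   CTCAE v5 style table.
#' @return Integer grade(s) in 0..4: the number of thresholds strictly
#'   above the value.
#' @export
grade_analyte <- function(value, analyte, table = default_grade_table()) {
  analyte <- match.arg(analyte, ht_analytes())
  if (any(value < 0)) stop("counts must be nonnegative")
  th <- table$thresholds[[analyte]]
  vapply(value, function(v) sum(th > v), integer(1))
}

#' Hematologic toxicity result for one patient
#'
#' Grades the four cytopenias from the series nadirs; the overall HT
#' grade is their maximum, and patients with overall grade >= 3 form the
#' G3+ group (grade 0-2 otherwise).
#'
#' @param series Blood series data frame.
#' @inheritParams grade_analyte
#' @param include_baseline Passed to [nadir()].
#' @return Object of class `ht_result` with per-toxicity grades
#'   (`leukopenia`, `neutropenia`, `anemia`, `thrombocytopenia`),
#'   `overall_grade` and `group` (`"G0_2"` / `"G3plus"`).
#' @export
ht_result <- function(series, table = default_grade_table(),
                      include_baseline = TRUE) {
  grades <- vapply(ht_analytes(), function(an)
    grade_analyte(nadir(series, an, include_baseline), an, table),
    integer(1))
  names(grades) <- unname(ht_toxicities()[ht_analytes()])
  overall <- max(grades)
  structure(
    c(as.list(grades),
      list(overall_grade = overall,
           group = if (overall >= 3) "G3plus" else "G0_2")),
    class = "ht_result")
}

#' @export
print.ht_result <- function(x, ...) {
  cat(sprintf(
    "<ht_result> leuko %d | neutro %d | anemia %d | thrombo %d -> HT grade %d (%s)\n",
    x$leukopenia, x$neutropenia, x$anemia, x$thrombocytopenia,
    x$overall_grade, x$group))
  invisible(x)
}

#' Grade a whole cohort of blood series
#'
#' @param blood Data frame of stacked series with a `patient_id` column
#'   plus the analyte columns; rows for one patient must be ordered by
#'   `day`.
#' @inheritParams ht_result
#' @return Data frame with one row per patient: `patient_id`, `g_leuko`,
#'   `g_neutro`, `g_anemia`, `g_thrombo`, `ht_grade`, `ht_group`.
#' @export
ht_table <- function(blood, table = default_grade_table(),
                     include_baseline = TRUE) {
  stopifnot("patient_id" %in% names(blood))
  ids <- unique(blood$patient_id)
  rows <- lapply(ids, function(id) {
    r <- ht_result(blood[blood$patient_id == id, , drop = FALSE],
                   table, include_baseline)
    data.frame(patient_id = id, g_leuko = r$leukopenia,
               g_neutro = r$neutropenia, g_anemia = r$anemia,
               g_thrombo = r$thrombocytopenia,
               ht_grade = r$overall_grade, ht_group = r$group,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Toxicity grade distribution in the layout of a summary table
#'
#' Counts patients per grade (0-4) for overall HT and each cytopenia.
#'
#' @param ht Data frame from [ht_table()].
#' @return Integer matrix, rows = toxicity (All, leukopenia, neutropenia,
#'   anemia, thrombocytopenia), columns = grades 0..4.
#' @export
ht_grade_distribution <- function(ht) {
  cnt <- function(g) tabulate(factor(g, levels = 0:4), nbins = 5L)
  m <- rbind(All = cnt(ht$ht_grade),
             leukopenia = cnt(ht$g_leuko),
             neutropenia = cnt(ht$g_neutro),
             anemia = cnt(ht$g_anemia),
             thrombocytopenia = cnt(ht$g_thrombo))
  colnames(m) <- paste0("grade", 0:4)
  m
}
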