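#' Binary logistic regression with odds ratios and Wald intervals
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares
#' via [stats::glm()]) of a binary outcome on a mix of continuous and
#' categorical predictors. Categorical terms use treatment (dummy) coding
#' against a declared reference level — for the grouped BM_ACT% predictor
#' the natural reference is the 30%-40% group, so the below-30% and
#' above-40% effects are read against it. Odds ratios are `exp(coef)`
#' with Wald intervals `exp(coef +/- z * SE)`. Nonconvergence and
#' (quasi-)separation are detected and reported on the fit object rather
#' than silently accepted.
#'
#' @param formula Model formula; the response must be binary (0/1,
#'   logical, or a two-level factor).
#' @param data Data frame of per-subject records.
#' @param ref_levels Named list mapping categorical predictor names to
#'   their reference level, e.g. `list(bm_group = "MID30_40")`.
#' @param conf_level Wald interval coverage, default 0.95.
#' @return Object of class `logistic_fit` with a per-term data frame
#'   (`term`, `estimate` (log-odds), `se`, `or`, `ci_lo`, `ci_hi`, `p`),
#'   `converged`, `separation`, and the underlying `glm` fit.
#' @export
logistic_fit <- function(formula, data, ref_levels = NULL,
                         conf_level = 0.95) {
  stopifnot(is.data.frame(data))
  for (v in names(ref_levels)) {
    if (!v %in% names(data)) stop("ref level given for absent term: ", v)
    data[[v]] <- stats::relevel(factor(data[[v]]), ref = ref_levels[[v]])
  }
  yname <- all.vars(formula)[1]
  y <- data[[yname]]
  if (is.factor(y) || is.character(y)) {
    y <- factor(y)
    if (nlevels(y) != 2L) stop("outcome must have exactly two levels")
    data[[yname]] <- as.integer(y == levels(y)[2])
  }
  if (length(unique(data[[yname]])) != 2L)
    stop("outcome must contain both classes")
  warned_sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warned_sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (length(stats::coef(fit)) >= nrow(data))
    stop("more parameters than observations")
  if (anyNA(stats::coef(fit))) stop("singular design matrix")
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  separation <- warned_sep || any(abs(sm[, "Estimate"]) > 15)
  terms <- data.frame(
    term = rownames(sm),
    estimate = sm[, "Estimate"], se = sm[, "Std. Error"],
    or = exp(sm[, "Estimate"]),
    ci_lo = exp(sm[, "Estimate"] - z * sm[, "Std. Error"]),
    ci_hi = exp(sm[, "Estimate"] + z * sm[, "Std. Error"]),
    p = sm[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(terms = terms, converged = fit$converged,
                 separation = separation, conf_level = conf_level,
                 fit = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit>",
      if (!x$converged) "NOT CONVERGED" else "",
      if (x$separation) "(possible separation)" else "", "\n")
  df <- x$terms
  df$or <- signif(df$or, 4); df$ci_lo <- signif(df$ci_lo, 4)
  df$ci_hi <- signif(df$ci_hi, 4); df$p <- signif(df$p, 3)
  print(df[, c("term", "or", "ci_lo", "ci_hi", "p")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.logistic_fit <- function(object, ...) {
  print(object)
  invisible(object$terms)
}

#' @export
coef.logistic_fit <- function(object, ...) {
  stats::setNames(object$terms$estimate, object$terms$term)
}

# continuous / categorical covariates recognised by the univariate battery
table3_continuous <- function()
  c("age", "bmi", "max_diameter", "bm_act_cm3", "bm_act_pct",
    "suvmax", "mtv_cm3", "tlg")
table3_categorical <- function()
  c("figo", "differentiation", "parametrial_invasion", "ln_metastasis")

#' Univariate HT analysis battery with grouped BM_ACT% post-hoc
#'
#' Runs the full univariate comparison of covariates between the grade
#' 0-2 and grade 3+ HT groups: [compare_continuous()] for each continuous
#' covariate present, [chi2_test()] (automatic correction) for each
#' categorical covariate, the 3 x 2 grouped BM_ACT% x HT cross-tab with
#' its overall chi-square, and all three pairwise 2 x 2 group comparisons
#' with raw and Holm-adjusted p-values. Variables with univariate
#' `p < screen_p` (default 0.1) are flagged for the multivariable
#' logistic model.
#'
#' @param cohort Data frame with `ht_group` (`"G0_2"` / `"G3plus"`),
#'   `bm_group` (`"LT30"` / `"MID30_40"` / `"GT40"`), and any of the
#'   covariate columns `age`, `bmi`, `max_diameter`, `bm_act_cm3`,
#'   `bm_act_pct`, `suvmax`, `mtv_cm3`, `tlg`, `figo`, `differentiation`,
#'   `parametrial_invasion`, `ln_metastasis`.
#' @param screen_p Screening threshold for carrying variables forward,
#'   default 0.1.
#' @return List of class `table3_analysis`: `univariate` (data frame:
#'   variable, method, statistic, p), `crosstab` (3 x 2 matrix),
#'   `overall` (`ht_test` for the 3 x 2 table), `pairwise` (data frame
#'   with raw and Holm-adjusted p per 2 x 2 comparison), and `screened`
#'   (variables passing the screen).
#' @export
build_table3 <- function(cohort, screen_p = 0.1) {
  stopifnot(all(c("ht_group", "bm_group") %in% names(cohort)))
  g0 <- cohort$ht_group == "G0_2"; g3 <- cohort$ht_group == "G3plus"
  if (!any(g0) || !any(g3)) stop("both HT groups must be present")

  rows <- list()
  for (v in intersect(table3_continuous(), names(cohort))) {
    r <- compare_continuous(cohort[[v]][g0], cohort[[v]][g3])
    rows[[v]] <- data.frame(variable = v, method = r$method,
                            statistic = r$statistic, p = r$p_value)
  }
  for (v in intersect(table3_categorical(), names(cohort))) {
    tab <- table(cohort[[v]], cohort$ht_group)
    r <- chi2_test(tab, "auto")
    rows[[v]] <- data.frame(variable = v, method = r$method,
                            statistic = r$statistic, p = r$p_value)
  }

  ct <- table(factor(cohort$bm_group, levels = bm_group_levels()),
              factor(cohort$ht_group, levels = c("G0_2", "G3plus")))
  crosstab <- matrix(as.integer(ct), nrow = 3,
                     dimnames = dimnames(ct))
  overall <- chi2_test(crosstab, "none")
  rows[["bm_group"]] <- data.frame(variable = "bm_group",
                                   method = overall$method,
                                   statistic = overall$statistic,
                                   p = overall$p_value)
  univariate <- do.call(rbind, rows); rownames(univariate) <- NULL

  pairs <- list(LT30_vs_MID30_40 = c("LT30", "MID30_40"),
                MID30_40_vs_GT40 = c("MID30_40", "GT40"),
                LT30_vs_GT40 = c("LT30", "GT40"))
  pw <- lapply(names(pairs), function(nm) {
    sub <- crosstab[pairs[[nm]], , drop = FALSE]
    r <- chi2_test(sub, "auto")
    data.frame(comparison = nm, method = r$method, statistic = r$statistic,
               p_raw = r$p_value)
  })
  pairwise <- do.call(rbind, pw)
  pairwise$p_holm <- holm_bonferroni(pairwise$p_raw)

  structure(list(univariate = univariate, crosstab = crosstab,
                 overall = overall, pairwise = pairwise,
                 screened = univariate$variable[univariate$p < screen_p],
                 screen_p = screen_p),
            class = "table3_analysis")
}

#' @export
print.table3_analysis <- function(x, ...) {
  cat("Univariate comparisons (G0-2 vs G3+):\n")
  u <- x$univariate
  u$statistic <- signif(u$statistic, 4); u$p <- signif(u$p, 3)
  print(u, row.names = FALSE)
  cat("\nGrouped BM_ACT% x HT cross-tab:\n"); print(x$crosstab)
  cat(sprintf("\nOverall: chi2 = %.3f, p = %.3f\n",
              x$overall$statistic, x$overall$p_value))
  cat("\nPairwise 2x2 comparisons:\n")
  p <- x$pairwise
  p$statistic <- signif(p$statistic, 4)
  p$p_raw <- signif(p$p_raw, 3); p$p_holm <- signif(p$p_holm, 3)
  print(p, row.names = FALSE)
  cat(sprintf("\nScreened at p < %g: %s\n", x$screen_p,
              paste(x$screened, collapse = ", ")))
  invisible(x)
}
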