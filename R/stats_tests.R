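#' Construct a test result record
#' @keywords internal
test_result <- function(method, statistic, p_value, correction = FALSE,
                        notes = "", extra = list()) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(c(list(method = method, statistic = unname(statistic),
                   p_value = min(unname(p_value), 1),
                   correction = correction, notes = notes), extra),
            class = "ht_test")
}

#' @export
print.ht_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g%s%s\n", x$method,
              x$statistic, x$p_value,
              if (isTRUE(x$correction)) " (continuity-corrected)" else "",
              if (nzchar(x$notes)) paste0(" [", x$notes, "]") else ""))
  invisible(x)
}

#' Normality gate (Lilliefors-corrected Kolmogorov-Smirnov)
#'
#' One-sample KS test against a normal with mean and SD estimated from
#' the sample, with the Lilliefors small-sample correction (the behavior
#' of common statistical packages when a KS normality test is requested).
#' The sample is called compatible with normality when `p >= 0.05`; this
#' is the gate used to choose parametric vs rank-based two-sample and
#' paired tests.
#'
#' @param x Numeric sample, `n >= 5`, non-degenerate.
#' @return `ht_test` with method `"ks_normality"`, the D statistic and
#'   p-value, plus field `normal` (logical gate at 0.05).
#' @export
ks_normality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 5L) stop("need at least 5 observations")
  if (stats::sd(x) == 0) stop("degenerate sample (zero variance)")
  lt <- nortest::lillie.test(x)
  test_result("ks_normality", lt$statistic, lt$p.value,
              extra = list(normal = lt$p.value >= 0.05))
}

# gate helper: TRUE = treat as normal. Samples too small for the
# Lilliefors test (n < 5) are treated as normal; constant samples as
# non-normal (rank test handles ties).
is_normalish <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 5L) return(TRUE)
  if (stats::sd(x) == 0) return(FALSE)
  nortest::lillie.test(x)$p.value >= 0.05
}

# Mann-Whitney U with tie-corrected asymptotic Z, no continuity
# correction. Z is signed from the first sample's U.
mann_whitney_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (v <= 0) return(list(u = u1, z = 0, p = 1))
  z <- (u1 - mu) / sqrt(v)
  list(u = u1, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare a continuous variable between two groups
#'
#' Both samples are passed through the normality gate ([ks_normality()];
#' samples with `n < 5` are treated as normal). If both pass, a two-sided
#' pooled-variance Student t-test is used; otherwise a Mann-Whitney U test
#' reported as a tie-corrected asymptotic Z without continuity correction.
#' The method choice is a pure function of the two samples and is recorded
#' in the result.
#'
#' @param x,y Numeric samples, each with `n >= 2`.
#' @return `ht_test` with method `"t"` (statistic = t, extra `df`) or
#'   `"mann_whitney_u"` (statistic = Z, extra `u`).
#' @export
compare_continuous <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 in each group")
  if (is_normalish(x) && is_normalish(y)) {
    if (stats::sd(c(x, y)) == 0)
      return(test_result("t", 0, 1, extra = list(df = length(x) + length(y) - 2)))
    tt <- stats::t.test(x, y, var.equal = TRUE)
    test_result("t", tt$statistic, tt$p.value,
                extra = list(df = unname(tt$parameter)))
  } else {
    mw <- mann_whitney_z(x, y)
    test_result("mann_whitney_u", mw$z, mw$p, extra = list(u = mw$u))
  }
}

#' Paired baseline-vs-nadir comparison
#'
#' The within-patient differences go through the normality gate: paired t
#' when compatible with normality, Wilcoxon signed-rank otherwise (or on
#' request). The signed-rank statistic is the positive-rank sum of
#' `nadir - baseline` with the asymptotic two-sided p (no continuity
#' correction); ties and zeros follow the standard normal-approximation
#' treatment.
#'
#' @param baseline,nadir Equal-length numeric vectors, `n >= 2`.
#' @param method `"auto"` (gate on differences), `"paired_t"` or
#'   `"signed_rank"`.
#' @return `ht_test` with method `"paired_t"` (statistic = t) or
#'   `"wilcoxon_signed_rank"` (statistic = W, the positive-rank sum).
#' @export
paired_change <- function(baseline, nadir,
                          method = c("auto", "paired_t", "signed_rank")) {
  method <- match.arg(method)
  if (length(baseline) != length(nadir)) stop("length mismatch")
  if (length(baseline) < 2L) stop("need n >= 2 pairs")
  d <- nadir - baseline
  if (all(d == 0)) {
    m <- if (method == "signed_rank") "wilcoxon_signed_rank" else "paired_t"
    return(test_result(m, 0, 1, notes = "all differences zero"))
  }
  if (method == "auto")
    method <- if (is_normalish(d)) "paired_t" else "signed_rank"
  if (method == "paired_t") {
    tt <- stats::t.test(nadir, baseline, paired = TRUE)
    test_result("paired_t", tt$statistic, tt$p.value,
                extra = list(df = unname(tt$parameter)))
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(d, exact = FALSE, correct = FALSE))
    test_result("wilcoxon_signed_rank", wt$statistic, wt$p.value)
  }
}

#' Pearson chi-square test with automatic continuity correction
#'
#' Pearson chi-square on an r x c contingency table. Under `"auto"`, the
#' Yates continuity correction is applied exactly when the table is 2 x 2
#' and its smallest expected count is below 5; `"none"` and `"yates"`
#' force the uncorrected and corrected 2 x 2 variants.
#'
#' @param tab Integer matrix of counts (r, c >= 2) with positive margins.
#' @param correction `"auto"`, `"none"` or `"yates"`.
#' @return `ht_test` with method `"chi2"` or `"chi2_yates"`, the
#'   statistic, p-value and extras `df` and `min_expected`.
#' @export
chi2_test <- function(tab, correction = c("auto", "none", "yates")) {
  correction <- match.arg(correction)
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be nonnegative integers")
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("need at least a 2 x 2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has a zero margin")
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  is2x2 <- nrow(tab) == 2L && ncol(tab) == 2L
  yates <- switch(correction,
                  none = FALSE,
                  yates = if (is2x2) TRUE else stop("Yates correction needs a 2 x 2 table"),
                  auto = is2x2 && min(E) < 5)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  test_result(if (yates) "chi2_yates" else "chi2",
              ct$statistic, ct$p.value, correction = yates,
              extra = list(df = unname(ct$parameter), min_expected = min(E)))
}

#' Fisher exact test for a 2 x 2 table
#'
#' Two-sided exact p: the sum of hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed the
#' observed table's.
#'
#' @param tab 2 x 2 integer matrix with positive margins.
#' @return `ht_test` with method `"fisher"`; statistic is the conditional
#'   MLE odds ratio.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("Fisher exact test needs a 2 x 2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has a zero margin")
  ft <- stats::fisher.test(tab, conf.int = FALSE)
  test_result("fisher", unname(ft$estimate), ft$p.value)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down familywise-error adjustment with monotonicity enforcement;
#' the output is in the same order as the input.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
holm_bonferroni <- function(p_values) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p_values, method = "holm")
}
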