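test_that("normality gate accepts normal and rejects uniform samples", {
  set.seed(123)
  r_norm <- ks_normality(rnorm(500))
  expect_gte(r_norm$p_value, 0.05)
  expect_true(r_norm$normal)
  r_unif <- ks_normality(runif(500) * 10)
  expect_lt(r_unif$p_value, 0.05)
  expect_false(r_unif$normal)
  expect_error(ks_normality(rep(2, 10)), "degenerate")
  expect_error(ks_normality(c(1, 2, 3)), "at least 5")
})

test_that("two-group comparison picks t or Mann-Whitney by the gate", {
  # identical groups, t path: t = 0, p = 1
  x <- c(1, 2, 3, 4)
  r <- compare_continuous(x, x)
  expect_identical(r$method, "t")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # pooled-variance closed form on a 3+3 fixture
  a <- c(1, 2, 3); b <- c(2, 4, 9)
  rt <- compare_continuous(a, b)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_identical(rt$method, "t")
  expect_equal(rt$statistic, t_hand, tolerance = 1e-12)

  # clearly non-normal large samples take the U path
  set.seed(21)
  xl <- exp(rnorm(300, 0, 1.5)); yl <- exp(rnorm(300, 0.5, 1.5))
  ru <- compare_continuous(xl, yl)
  expect_identical(ru$method, "mann_whitney_u")

  # gate is a deterministic function of the samples
  expect_identical(compare_continuous(xl, yl)$method, ru$method)
  expect_equal(compare_continuous(xl, yl)$p_value, ru$p_value)
})

test_that("Mann-Whitney matches the exhaustive rank-assignment oracle", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  mw <- pelvimarrow:::mann_whitney_z(x, y)
  expect_equal(mw$u, 0)
  # enumeration of all 20 rank assignments: P(U <= 0) = 1/20
  combos <- combn(6, 3)
  u_all <- apply(combos, 2, function(ix) sum(ix) - 6)
  expect_equal(mean(u_all <= 0), 1 / 20)
  # tie-corrected asymptotic p agrees with the standard implementation
  set.seed(31)
  for (rep in 1:10) {
    xx <- sample(1:6, 12, replace = TRUE)   # heavy ties
    yy <- sample(2:8, 9, replace = TRUE)
    got <- pelvimarrow:::mann_whitney_z(xx, yy)
    ref <- suppressWarnings(wilcox.test(xx, yy, exact = FALSE,
                                        correct = FALSE))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    expect_equal(got$u, unname(ref$statistic))
  }
})

test_that("paired comparison handles the gate, zeros and signed ranks", {
  b <- c(5, 6, 7, 8)
  r0 <- paired_change(b, b)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # signed-rank statistic on differences [1, 2, 3, -1]
  base <- c(0, 0, 0, 0); nad <- c(1, 2, 3, -1)
  rs <- paired_change(base, nad, method = "signed_rank")
  # oracle: |d| ranks with ties -> positive-rank sum
  d <- nad - base
  rk <- rank(abs(d))
  expect_equal(rs$statistic, sum(rk[d > 0]))  # 1.5 + 3 + 4 = 8.5
  # exact sign-flip enumeration brackets the asymptotic p sensibly
  w_all <- vapply(0:15, function(bits) {
    signs <- ifelse(bitwAnd(bits, 2^(0:3)) > 0, 1, -1)
    sum(rk[signs > 0])
  }, numeric(1))
  p_exact <- mean(abs(w_all - mean(w_all)) >= abs(sum(rk[d > 0]) - mean(w_all)))
  expect_gt(p_exact, 0.05)   # n = 4 cannot be significant
  expect_gt(rs$p_value, 0.05)

  expect_error(paired_change(1:3, 1:4), "length")
})

test_that("chi-square applies the automatic 2x2 continuity rule", {
  t1 <- matrix(c(10, 3, 3, 10), 2, byrow = TRUE)   # min expected 6.5
  t2 <- matrix(c(3, 10, 9, 6), 2, byrow = TRUE)    # min expected 5.57
  t3 <- matrix(c(10, 3, 9, 6), 2, byrow = TRUE)    # min expected 4.18
  r1 <- chi2_test(t1, "auto"); r2 <- chi2_test(t2, "auto")
  r3 <- chi2_test(t3, "auto")
  expect_identical(r1$method, "chi2")
  expect_identical(r2$method, "chi2")
  expect_identical(r3$method, "chi2_yates")   # auto triggers Yates
  expect_equal(round(r1$statistic, 3), 7.538)
  expect_equal(round(r2$statistic, 3), 3.877)
  expect_equal(round(r3$statistic, 3), 0.303)
  # forcing the variants
  E3 <- outer(rowSums(t3), colSums(t3)) / sum(t3)
  expect_equal(chi2_test(t3, "none")$statistic, sum((t3 - E3)^2 / E3))
  # identical row proportions -> 0
  expect_equal(chi2_test(matrix(c(4, 8, 2, 4), 2), "none")$statistic, 0)
  expect_error(chi2_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "margin")
  expect_error(chi2_test(matrix(1:9, 3), "yates"), "2 x 2")
})

test_that("chi-square equals the textbook formula on random tables", {
  set.seed(77)
  for (rep in 1:200) {
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    tab <- matrix(rpois(nr * nc, 6) + 1, nr, nc)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(chi2_test(tab, "none")$statistic,
                 sum((tab - E)^2 / E), tolerance = 1e-10)
  }
})

test_that("Fisher exact equals hypergeometric enumeration", {
  r <- fisher_exact(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(5, 2, 2))$p_value, 1)

  # enumeration oracle over random tables
  set.seed(13)
  for (rep in 1:50) {
    tab <- matrix(sample(1:10, 4, replace = TRUE), 2)
    m <- rowSums(tab); k <- colSums(tab)
    a_range <- max(0, k[1] - m[2]):min(m[1], k[1])
    probs <- dhyper(a_range, m[1], m[2], k[1])
    p_obs <- dhyper(tab[1, 1], m[1], m[2], k[1])
    p_or <- sum(probs[probs <= p_obs * (1 + 1e-7)])
    expect_equal(fisher_exact(tab)$p_value, min(p_or, 1),
                 tolerance = 1e-10)
  }
  expect_error(fisher_exact(matrix(1:9, 3)), "2 x 2")
})

test_that("Holm adjustment is step-down, monotone and order-preserving", {
  expect_equal(holm_bonferroni(0.03), 0.03)
  expect_equal(holm_bonferroni(c(0.006, 0.049, 0.582)),
               c(0.018, 0.098, 0.582))
  expect_equal(holm_bonferroni(rep(0.02, 4)), rep(0.08, 4))
  set.seed(3)
  for (rep in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holm_bonferroni(p)
    expect_true(all(adj[order(p)] == cummax(adj[order(p)])))
    expect_true(all(adj <= pmin(length(p) * p, 1) + 1e-12))
    expect_true(all(adj >= p))
  }
  expect_error(holm_bonferroni(c(0.5, 1.2)), "0, 1")
})

test_that("logistic fit reproduces crude odds ratios and detects nulls", {
  # single binary predictor from the 2x2 table [[10,3],[3,10]]
  df <- data.frame(
    grp = rep(c("LT30", "MID30_40"), times = c(13, 13)),
    ht = c(rep(0, 10), rep(1, 3), rep(0, 3), rep(1, 10)))
  fit <- logistic_fit(ht ~ grp, df, ref_levels = list(grp = "MID30_40"))
  or_lt30 <- fit$terms$or[fit$terms$term == "grpLT30"]
  expect_equal(or_lt30, (3 / 10) / (10 / 3), tolerance = 1e-6)  # 9/100
  expect_true(fit$converged)
  expect_false(fit$separation)
  expect_equal(coef(fit)[["grpLT30"]], log(9 / 100), tolerance = 1e-6)

  # independent outcome: all CIs cover 1
  set.seed(42)
  dn <- data.frame(x = rnorm(2000), g = sample(c("a", "b"), 2000, TRUE),
                   y = rbinom(2000, 1, 0.4))
  fn <- logistic_fit(y ~ x + g, dn)
  slopes <- fn$terms[fn$terms$term != "(Intercept)", ]
  expect_true(all(slopes$ci_lo < 1 & slopes$ci_hi > 1))

  # separation is reported, not silently accepted
  ds <- data.frame(x = c(rep(0, 10), rep(1, 10)),
                   y = c(rep(0, 10), rep(1, 10)))
  fs <- logistic_fit(y ~ x, ds)
  expect_true(fs$separation)

  expect_error(logistic_fit(y ~ x, data.frame(x = 1:5, y = rep(1, 5))),
               "both classes")
})

test_that("the univariate battery is order-invariant and screens at 0.1", {
  co <- realize_table3_cohort()$cohort
  t3 <- build_table3(co)
  expect_equal(round(t3$pairwise$statistic, 3), c(7.538, 3.877, 0.303))
  expect_equal(t3$pairwise$p_holm, holm_bonferroni(t3$pairwise$p_raw))
  expect_true("bm_group" %in% t3$screened)

  # permuting patient order changes nothing
  set.seed(8)
  t3p <- build_table3(co[sample(nrow(co)), ])
  expect_equal(t3p$univariate, t3$univariate)
  expect_equal(t3p$crosstab, t3$crosstab)
  expect_equal(t3p$pairwise, t3$pairwise)

  # covariates independent of outcome rarely pass the screen
  set.seed(99)
  hits <- replicate(20, {
    n <- 41
    coh <- data.frame(
      age = rnorm(n, 52, 10), bmi = rnorm(n, 22.6, 3),
      ht_group = sample(rep(c("G0_2", "G3plus"), c(22, 19))),
      bm_group = sample(rep(c("LT30", "MID30_40", "GT40"), c(13, 13, 15))))
    u <- build_table3(coh)$univariate
    any(u$p[u$variable %in% c("age", "bmi")] < 0.1)
  })
  expect_lt(mean(hits), 0.5)
})
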