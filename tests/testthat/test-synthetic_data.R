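test_that("phantom generation is deterministic and carries exact truth", {
  cfg <- small_phantom_config()
  ph1 <- generate_phantom(cfg)
  ph2 <- generate_phantom(cfg)
  expect_identical(ph1$ct$values, ph2$ct$values)
  expect_identical(ph1$pet$values, ph2$pet$values)

  # a different seed moves the active voxels but not the counts
  ph3 <- generate_phantom(small_phantom_config(seed = 2))
  expect_identical(ph3$truth, ph1$truth)
  expect_false(identical(ph3$pet$values, ph1$pet$values))

  expect_error(phantom_config(bone = list(outer_r = 500, inner_r = 38,
                                          z = c(20, 100))), "fit")
  expect_error(phantom_config(marrow = list(active_fraction = 1.2,
                                            suv_hi = 3, suv_lo = 0.5)),
               "active_fraction")
})

test_that("the pipeline recovers the phantom's constructed parameters", {
  ph <- generate_phantom(small_phantom_config())
  bone <- segment_bone(ph$ct, ph$roi)
  expect_equal(sum(bone$values), ph$truth$n_bone)
  bm <- compute_bm_metrics(ph$pet, bone)
  expect_identical(bm$bm_act_pct, ph$truth$bm_act_pct)
  # realized fraction is the requested one up to voxel quantization
  expect_lt(abs(ph$truth$active_fraction - ph$truth$requested_fraction),
            1 / ph$truth$n_bone)
  tm <- tumor_metrics(ph$pet, ph$voi)
  expect_identical(tm$suvmax, ph$truth$suvmax)

  # recovery holds across generating fractions (hi/lo straddle the mean)
  for (f in c(0.2, 0.5, 0.8)) {
    phf <- generate_phantom(small_phantom_config(
      marrow = list(active_fraction = f, suv_hi = 3, suv_lo = 0.5)))
    bmf <- compute_bm_metrics(phf$pet, segment_bone(phf$ct, phf$roi))
    expect_identical(bmf$bm_act_pct, phf$truth$bm_act_pct)
  }
})

test_that("cohort generation is deterministic and grades round-trip", {
  cfg <- cohort_config(n = 60, seed = 5)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$cohort, c2$cohort)
  expect_identical(c1$blood, c2$blood)

  # re-grading the generated series reproduces the intended grades
  ig <- attr(c1$cohort, "intended_grades")
  expect_equal(c1$cohort$g_leuko, ig$wbc)
  expect_equal(c1$cohort$g_neutro, ig$anc)
  expect_equal(c1$cohort$g_anemia, ig$hgb)
  expect_equal(c1$cohort$g_thrombo, ig$plt)
  expect_equal(c1$cohort$ht_grade, ig$overall)

  # group labels consistent with the generated BM_ACT%
  expect_identical(c1$cohort$bm_group,
                   classify_bm_act_group(c1$cohort$bm_act_pct))

  # degenerate config: zero G3+ probability everywhere
  c0 <- generate_cohort(cohort_config(n = 30, seed = 1,
                                      g3_prob_by_group = c(0, 0, 0)))
  expect_true(all(c0$cohort$ht_group == "G0_2"))
})

test_that("the fixture cohort realizes the target cross-tab and grades", {
  co <- realize_table3_cohort()
  tab <- table(factor(co$cohort$bm_group,
                      levels = c("LT30", "MID30_40", "GT40")),
               factor(co$cohort$ht_group, levels = c("G0_2", "G3plus")))
  expect_equal(matrix(as.integer(tab), 3),
               matrix(c(10, 3, 9, 3, 10, 6), 3))

  dist <- ht_grade_distribution(co$cohort)
  expect_equal(unname(dist["All", ]), c(2, 2, 18, 15, 4))
  expect_equal(unname(dist["leukopenia", ]), c(3, 7, 17, 13, 1))
  expect_equal(unname(dist["neutropenia", ]), c(14, 6, 8, 10, 3))
  expect_equal(unname(dist["anemia", ]), c(14, 7, 16, 4, 0))
  expect_equal(unname(dist["thrombocytopenia", ]), c(21, 7, 10, 1, 2))

  # deterministic: two calls agree; marginals of covariates as configured
  expect_identical(realize_table3_cohort()$cohort, co$cohort)
  expect_equal(sort(as.integer(table(co$cohort$figo))), sort(c(6L, 32L, 3L)))
  expect_identical(co$cohort$bm_group,
                   classify_bm_act_group(co$cohort$bm_act_pct))
})

test_that("logistic simulation matches its generating model at scale", {
  d <- simulate_logistic_cohort(20000, seed = 4)
  fit <- logistic_fit(ht ~ suvmax + bm_group, d,
                      ref_levels = list(bm_group = "MID30_40"))
  est <- coef(fit)
  expect_equal(unname(est["suvmax"]), 0.1, tolerance = 0.15)
  expect_equal(unname(est["bm_groupLT30"]), 1, tolerance = 0.15)
  expect_equal(unname(est["bm_groupGT40"]), -1, tolerance = 0.15)
})
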