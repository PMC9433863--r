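test_that("ellipsoid rasterization matches the brute-force center test", {
  grid <- uniform_vol(1, c(11, 11, 11), spacing = c(3, 3, 3))
  # sphere radius 9 mm centered on the middle voxel center (15,15,15) mm
  voi <- ellipsoid_voi(c(15, 15, 15), c(9, 9, 9))
  m <- voi_mask(voi, grid)
  expect_equal(sum(m$values), 123L)   # lattice points with |x|^2 <= 9

  # exhaustive oracle over all voxel centers
  oracle <- array(FALSE, c(11, 11, 11))
  for (i in 1:11) for (j in 1:11) for (k in 1:11) {
    x <- (c(i, j, k) - 1) * 3
    oracle[i, j, k] <- sum(((x - 15) / 9)^2) <= 1
  }
  expect_identical(m$values, oracle)

  big <- voi_mask(ellipsoid_voi(c(15, 15, 15), c(1e4, 1e4, 1e4)), grid)
  expect_true(all(big$values))
  expect_error(voi_mask(ellipsoid_voi(c(-50, -50, -50), c(2, 2, 2)), grid),
               "intersect")
})

test_that("SUVmax is the maximum over the VOI", {
  pet <- uniform_vol(2.5, c(9, 9, 9))
  m <- full_mask(pet)
  expect_equal(suv_max(pet, m), 2.5)
  vals <- pet$values; vals[4, 5, 6] <- 17.5
  hot <- image_volume(vals, pet$spacing, "PET")
  expect_equal(suv_max(hot, m), 17.5)
  expect_equal(suv_max(hot, m), max(vals[m$values]))  # linear-scan oracle
})

test_that("MTV segmentation is a strict 40% SUVmax threshold", {
  pet <- uniform_vol(5, c(7, 7, 7))
  m <- full_mask(pet)
  expect_true(all(segment_mtv(pet, m)$values))  # u > 0.4u everywhere

  vals <- array(3.9, c(7, 7, 7)); vals[4, 4, 4] <- 10
  pet2 <- image_volume(vals, c(3, 3, 3), "PET")
  m2 <- segment_mtv(pet2, full_mask(pet2))
  expect_equal(sum(m2$values), 1L)              # 3.9 < 4.0 strictly excluded
  expect_true(m2$values[4, 4, 4])

  # Gaussian lesion: voxel set equals the exhaustive comparison
  ph <- generate_phantom(small_phantom_config())
  vm <- voi_mask(ph$voi, ph$pet)
  mm <- segment_mtv(ph$pet, vm)
  smax <- suv_max(ph$pet, vm)
  expect_identical(mm$values, vm$values & (ph$pet$values > 0.4 * smax))
})

test_that("tumor metrics satisfy the TLG identity and uniform case", {
  pet <- uniform_vol(4, c(9, 9, 9))
  voi <- ellipsoid_voi(c(12, 12, 12), c(10, 10, 10))
  tm <- tumor_metrics(pet, voi)
  v_voi <- sum(voi_mask(voi, pet)$values) * 27 / 1000
  expect_equal(tm$mtv_cm3, v_voi)
  expect_equal(tm$tlg, 4 * v_voi)
  expect_equal(tm$tlg, tm$mtv_cm3 * tm$mtv_mean_suv, tolerance = 1e-12)
})

test_that("raising the MTV fraction never increases the volume", {
  set.seed(5)
  for (rep in 1:5) {
    vals <- array(rlnorm(9^3, 0, 1), c(9, 9, 9))
    pet <- image_volume(vals, c(3, 3, 3), "PET")
    voi <- ellipsoid_voi(c(12, 12, 12), c(11, 11, 11))
    mtvs <- vapply(c(0.2, 0.4, 0.6, 0.8),
                   function(f) tumor_metrics(pet, voi, f)$mtv_cm3,
                   numeric(1))
    expect_true(all(diff(mtvs) <= 0))
  }
})

test_that("discretized MTV approaches the analytic isocontour volume", {
  ph3 <- generate_phantom(phantom_config(spacing = c(3, 3, 3)))
  tm3 <- tumor_metrics(ph3$pet, ph3$voi)
  err3 <- abs(tm3$mtv_cm3 - ph3$truth$mtv_analytic_cm3) /
    ph3$truth$mtv_analytic_cm3
  ph15 <- generate_phantom(phantom_config(spacing = c(1.5, 1.5, 1.5)))
  tm15 <- tumor_metrics(ph15$pet, ph15$voi)
  err15 <- abs(tm15$mtv_cm3 - ph15$truth$mtv_analytic_cm3) /
    ph15$truth$mtv_analytic_cm3
  expect_lt(err15, err3)       # finer grid converges
  expect_lt(err15, 0.05)
})

test_that("interference clearing zeroes the mask and nothing else", {
  ph <- generate_phantom(small_phantom_config(
    bladder = list(center = c(60, 88, 60), radius = 10, suv = 30)))
  vm <- voi_mask(ph$voi, ph$pet)

  empty <- binary_mask(array(FALSE, dim(ph$pet$values)), ph$pet$spacing)
  expect_identical(clear_interference(ph$pet, empty)$values,
                   ph$pet$values)

  all_m <- full_mask(ph$pet)
  expect_true(all(clear_interference(ph$pet, all_m)$values == 0))

  # hot bladder inside the VOI dominates until cleared
  bl <- binary_mask(ph$pet$values >= 29, ph$pet$spacing)
  expect_gt(suv_max(ph$pet, vm), 17.5)
  tm <- tumor_metrics(ph$pet, ph$voi, interference = bl)
  expect_equal(tm$suvmax, 17.5)

  # locality: clearing a region disjoint from the VOI changes nothing
  far <- array(FALSE, dim(ph$pet$values)); far[1:3, 1:3, 1:3] <- TRUE
  far_m <- binary_mask(far, ph$pet$spacing)
  tm_clear <- tumor_metrics(ph$pet, ph$voi, interference = bl)
  pet2 <- clear_interference(ph$pet, far_m)
  tm2 <- tumor_metrics(pet2, ph$voi, interference = bl)
  expect_equal(tm2$mtv_cm3, tm_clear$mtv_cm3)
  expect_equal(tm2$tlg, tm_clear$tlg)
})
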