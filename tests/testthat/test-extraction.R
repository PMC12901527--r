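# Mask-to-profile extraction and standardization to the anatomical grid.

test_that("slice areas come from voxel counts times in-plane voxel area", {
  mask <- array(0L, dim = c(20, 20, 3))
  mask[1:10, 1:10, 2] <- 1L # 100 voxels
  sp <- compute_slice_areas(mask, c(1.4, 1.4, 3))
  expect_equal(sp$areas_cm2, c(0, 1.96, 0))
  expect_equal(sp$thickness_cm, 0.3)
  expect_equal(sp$vat_total_l, 1.96 * 0.3 / 1000)

  # empty mask: valid profile, zero volume, fractions flagged undefined
  empty <- compute_slice_areas(array(0L, dim = c(4, 4, 5)), c(1.4, 1.4, 3))
  expect_equal(empty$vat_total_l, 0)
  expect_true(all(is.na(empty$fractions)))

  # non-binary mask rejected
  bad <- array(0L, dim = c(4, 4, 2)); bad[1, 1, 1] <- 2L
  expect_error(compute_slice_areas(bad), "binary")
})

test_that("landmark centroids recover planted positions", {
  lm <- toy_landmarks()
  nz <- ceiling(max(lm) / 3) + 5
  vol <- array(0L, dim = c(16, 16, nz))
  for (k in seq_along(LANDMARK_LABELS)) {
    zi <- round(lm[[LANDMARK_LABELS[k]]] / 3) + 1
    vol[8, 8, zi] <- k # single-voxel labels
  }
  found <- locate_landmarks(vol, c(1.4, 1.4, 3))
  # centroid of a single-voxel label is that voxel's coordinate; planted
  # positions sit on slice centers so recovery is within half a slice
  expect_lte(max(abs(found - lm)), 1.5)
  # disc centers fall between adjacent vertebral centers
  expect_true(found[["L5/4"]] > found[["L5"]] && found[["L5/4"]] < found[["L4"]])

  vol0 <- vol; vol0[vol0 == 3L] <- 0L
  expect_error(locate_landmarks(vol0, c(1.4, 1.4, 3)), "L5/4")
})

test_that("uniform profiles standardize to equal values everywhere", {
  lm <- toy_landmarks()
  n <- ceiling((max(lm) + 30) / 3)
  pr <- slice_profile(rep(5, n))
  std <- standardize_profile(pr, lm)
  expect_length(std, 40)
  expect_true(all(abs(std - std[1]) < 1e-9))
})

test_that("caudal interpolation matches a dense-resampling oracle", {
  # linear-ramp areas: interpolation at the 26 caudal positions must match
  # a brute-force dense piecewise-linear resampling read off at the same
  # positions, to 1e-9 relative
  lm <- toy_landmarks()
  # L5 at FH + 125 mm puts all 26 caudal positions on the 0.1 mm grid
  lm <- spine_landmarks(replace(unclass(lm), 2, lm[["FH"]] + 125))
  n <- ceiling((max(lm) + 30) / 3)
  z <- (0:(n - 1)) * 3
  areas <- 2 + 0.05 * z
  pr <- slice_profile(areas)
  std <- standardize_profile(pr, lm)

  dense_oracle <- function(z, y, xout) {
    # independent piecewise-linear evaluator on a 0.01 cm grid
    zd <- seq(min(z), max(z), by = 0.1) # 0.01 cm = 0.1 mm
    yd <- numeric(length(zd))
    for (i in seq_along(zd)) {
      j <- findInterval(zd[i], z, rightmost.closed = TRUE)
      j <- min(max(j, 1), length(z) - 1)
      w <- (zd[i] - z[j]) / (z[j + 1] - z[j])
      yd[i] <- (1 - w) * y[j] + w * y[j + 1]
    }
    vapply(xout, function(x) yd[which.min(abs(zd - x))], numeric(1))
  }
  caudal_pos <- build_caudal_scale(lm, 26)
  # positions in the toy geometry are multiples of 0.1 mm within rounding,
  # so the dense grid passes through them
  oracle_vals <- dense_oracle(z, areas, caudal_pos) / sum(areas) * 100
  expect_equal(as.numeric(std[1:26]), oracle_vals, tolerance = 1e-9)
})

test_that("standardized profiles are invariant to area scaling", {
  set.seed(55)
  lm <- toy_landmarks()
  n <- ceiling((max(lm) + 30) / 3)
  areas <- runif(n, 0, 30)
  s1 <- standardize_profile(slice_profile(areas), lm)
  s2 <- standardize_profile(slice_profile(areas * 7.3), lm)
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-12)
})

test_that("vertebral spacing drops out up to the trunk-coverage scale", {
  # Two participants with the same anatomical shape but all geometry
  # scaled by a factor: grid locations of structure coincide, and the
  # per-slice percentages agree after rescaling by the covered length
  # (a longer trunk spreads total VAT over more slices).
  lm1 <- toy_landmarks()
  lm2 <- toy_landmarks(scale = 2)
  n1 <- ceiling((max(lm1) + 30) / 3)
  n2 <- ceiling((max(lm2) + 60) / 3)
  s1 <- standardize_profile(
    slice_profile(exp(-(((0:(n1 - 1)) * 3 - lm1[["L3"]]) / 40)^2)), lm1)
  # the dilated profile: same shape in relative coordinates, double width
  s2 <- standardize_profile(
    slice_profile(exp(-(((0:(n2 - 1)) * 3 - lm2[["L3"]]) / 80)^2)), lm2)
  expect_equal(names(which.max(s1)), names(which.max(s2)))
  expect_equal(as.numeric(s2) * 2, as.numeric(s1), tolerance = 0.02)
})

test_that("landmarks outside coverage raise a named error", {
  lm <- toy_landmarks()
  pr <- slice_profile(rep(1, 40)) # covers only 120 mm
  expect_error(standardize_profile(pr, lm), "Th10")
})
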