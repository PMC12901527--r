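# Synthetic cohort generator: participants, geometries, profiles, masks,
# exclusion planting.

test_that("participant draws are consistent and reproducible", {
  one <- generate_participants(1, seed = 5)
  expect_equal(nrow(one), 1)
  expect_equal(one$bmi, one$weight_kg / (one$height_cm / 100)^2,
               tolerance = 1e-9)

  a <- generate_participants(200, seed = 9)
  b <- generate_participants(200, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$bmi == a$weight_kg / (a$height_cm / 100)^2 |
                    abs(a$bmi - a$weight_kg / (a$height_cm / 100)^2) < 0.05))
  expect_true(all(a$vat_total_l >= 0))
  expect_true(all(a$age >= 20 & a$age <= 72))
})

test_that("cohort composition converges to the calibration table", {
  calib <- default_calibration()
  coh <- generate_participants(10000, seed = 31)
  men <- coh[coh$sex == "M", ]
  # men's group-II proportion ~ 2733/5681 within 3 binomial SEs
  p_hat <- mean(men$bmi >= 25 & men$bmi < 30)
  p_exp <- 2733 / 5681
  se <- sqrt(p_exp * (1 - p_exp) / nrow(men))
  expect_lt(abs(p_hat - p_exp), 3 * se)

  # men's overall VAT mean within 3 Monte-Carlo SEs of the calibration
  # mixture mean (the Monte-Carlo oracle)
  mcal <- calib[calib$sex == "M", ]
  vat_exp <- weighted.mean(mcal$vat_mean, mcal$n)
  se_vat <- sd(men$vat_total_l) / sqrt(nrow(men))
  expect_lt(abs(mean(men$vat_total_l) - vat_exp), 3 * se_vat)

  # invalid calibration is rejected with a message
  bad <- calib; bad$vat_sd[1] <- -1
  expect_error(generate_participants(10, calib = bad), "positive")
})

test_that("spine geometries are ordered, height-scaled and reproducible", {
  rec <- generate_participants(1, seed = 3)
  g1 <- generate_geometry(rec, seed = 11)
  g2 <- generate_geometry(rec, seed = 11)
  expect_identical(g1, g2)
  expect_true(all(diff(g1) > 0))

  # zero-sd distance: every draw exactly 12.9 cm
  g0 <- generate_geometry(rec, seed = 4, distance_sd = 0, spacing_jitter = 0)
  expect_equal((g0[["L5"]] - g0[["FH"]]) / 10, 12.9)

  # taller spine is longer
  tall <- rec; tall$height_cm <- 195
  short <- rec; short$height_cm <- 155
  gt <- generate_geometry(tall, seed = 8, distance_sd = 0, spacing_jitter = 0)
  gs <- generate_geometry(short, seed = 8, distance_sd = 0, spacing_jitter = 0)
  expect_gt(gt[["Th10"]] - gt[["L5"]], gs[["Th10"]] - gs[["L5"]])
})

test_that("true profiles conserve volume and respect the age model", {
  set.seed(21)
  coh <- generate_participants(10)
  geoms <- generate_geometries(coh)
  grid <- anatomical_grid()

  for (i in 1:5) {
    m <- default_profile_model(coh$sex[i], "II")
    pr <- generate_true_profile(coh[i, ], geoms[[i]], m, grid = grid)
    # conservation before voxelization: sum(area x thickness) = vat_total
    expect_equal(sum(pr$areas_cm2) * pr$thickness_cm / 1000,
                 coh$vat_total_l[i], tolerance = 1e-3)
    expect_true(all(pr$areas_cm2 >= 0))
    expect_equal(sum(pr$fractions), 1, tolerance = 1e-9)
  }

  # negative heights are rejected
  m_bad <- default_profile_model("M", "I")
  m_bad$pelvic_plateau <- -0.01
  expect_error(generate_true_profile(coh[1, ], geoms[[1]], m_bad), ">= 0")
})

test_that("noise-free age curves intersect exactly at the planted location", {
  set.seed(77)
  coh <- generate_participants(4)
  g <- generate_geometries(coh)[[1]]
  grid <- anatomical_grid()
  for (spec in list(c("M", "I"), c("M", "II"), c("F", "III"), c("F", "V"))) {
    m <- default_profile_model(spec[1], spec[2])
    m$noise_sd <- 0
    young <- coh[1, ]; young$age <- 25L
    old <- coh[1, ]; old$age <- 65L
    s_young <- standardize_profile(generate_true_profile(young, g, m), g, grid)
    s_old <- standardize_profile(generate_true_profile(old, g, m), g, grid)
    d <- s_young - s_old
    planted <- m$planted_intersection
    # exact agreement at the planted location, genuine differences nearby
    expect_lt(abs(d[[planted]]), 1e-9)
    expect_gt(max(abs(d)), 0.01)
    # closed-form oracle: the difference curve evaluated on the grid
    # attains its minimum magnitude at the planted location
    expect_equal(names(which.min(abs(d))), planted)
  }
})

test_that("zero age slopes produce identical curves at any age", {
  set.seed(12)
  coh <- generate_participants(2)
  g <- generate_geometries(coh)[[1]]
  m <- default_profile_model("M", "II")
  m$noise_sd <- 0
  m$age_slope_pelvic <- 0
  m$age_curvature <- 0
  m$deep_fraction_jitter <- 0
  r1 <- coh[1, ]; r1$age <- 25L
  r2 <- coh[1, ]; r2$age <- 65L
  p1 <- generate_true_profile(r1, g, m)
  p2 <- generate_true_profile(r2, g, m)
  expect_equal(p1$fractions, p2$fractions, tolerance = 1e-12)
})

test_that("men's default profiles peak at L3", {
  set.seed(8)
  calib <- default_calibration()
  coh <- generate_stratum_cohort("M", "II", 60)
  geoms <- generate_geometries(coh)
  grid <- anatomical_grid()
  m <- default_profile_model("M", "II")
  m$noise_sd <- 0
  profs <- build_profile_matrix(coh, geoms, grid, model_override = m)
  mean_curve <- colMeans(profs[, grid$labels])
  expect_equal(names(which.max(mean_curve)), "L3")
})

test_that("rendered masks reproduce requested areas within one voxel", {
  set.seed(14)
  coh <- generate_participants(2)
  g <- generate_geometries(coh)[[1]]
  m <- default_profile_model(coh$sex[1], "II")
  rec <- coh[1, ]
  rec$vat_total_l <- 2 # modest volume so a compact matrix suffices
  pr <- generate_true_profile(rec, g, m)
  vol <- render_mask(pr, g, dims_xy = c(128L, 128L))
  sp <- compute_slice_areas(vol$vat, vol$spacing)
  expect_lt(max(abs(sp$areas_cm2 - pr$areas_cm2)), 0.0196)

  # all-zero areas -> empty mask
  empty <- render_mask(rep(0, length(pr$areas_cm2)), g)
  expect_equal(sum(empty$vat), 0)

  # default spacing lands in the NIfTI header
  tmp <- tempfile(fileext = ".nii.gz")
  write_mask_nifti(vol, tmp)
  back <- read_mask_nifti(tmp)
  expect_equal(as.numeric(back$spacing), c(1.4, 1.4, 3), tolerance = 1e-6)
  expect_identical(back$data, vol$vat)

  # area larger than the field of view is rejected
  expect_error(render_mask(rep(1e4, 10), g), "field of view")
})

test_that("exclusion planting sets exact, disjoint counts", {
  coh <- generate_participants(800, seed = 19)
  out <- inject_exclusions(coh, list(fat_water_swap = 5, corrupted = 2,
                                     missing_anthropometry = 3), seed = 4)
  expect_equal(sum(out$flag_fat_water_swap), 5)
  expect_equal(sum(out$flag_corrupted), 2)
  expect_equal(sum(out$flag_missing_anthropometry), 3)
  # disjoint: nobody carries two flags
  expect_equal(sum(out$flag_fat_water_swap + out$flag_corrupted +
                     out$flag_missing_anthropometry), 10)

  # all-zero counts change nothing
  expect_identical(inject_exclusions(coh, list(fat_water_swap = 0)), coh)

  # round trip: apply_exclusions recovers the planted counts exactly
  res <- apply_exclusions(out)
  expect_equal(res$counts$n_removed[res$counts$criterion == "fat_water_swap"], 5L)
  expect_equal(res$counts$n_removed[res$counts$criterion == "corrupted"], 2L)
  expect_equal(
    res$counts$n_removed[res$counts$criterion == "missing_anthropometry"], 3L)

  expect_error(inject_exclusions(coh, list(bogus = 1)), "unknown")
})
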