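# Pipeline stages. Each stage reads the previous stage's files from
# config$out_dir, writes its own outputs there deterministically (all
# randomness flows from config$seed), and records a manifest with the
# config hash.

stage_paths <- function(config) {
  d <- config$out_dir
  list(
    cohort = file.path(d, "cohort.csv"),
    landmarks = file.path(d, "landmarks.csv"),
    slice_areas = file.path(d, "slice_areas.csv"),
    masks_dir = file.path(d, "masks"),
    profiles = file.path(d, "profiles.csv"),
    stratum_stats = file.path(d, "stratum_stats.csv"),
    factors_json = file.path(d, "factors.json"),
    factors_csv = file.path(d, "factors.csv"),
    cohort_summary = file.path(d, "cohort_summary.csv"),
    tests_summary = file.path(d, "tests_summary.csv"),
    distance_kde = file.path(d, "distance_kde.csv"),
    estimates = file.path(d, "estimates.csv"),
    validation = file.path(d, "validation.csv"),
    error_boxstats = file.path(d, "error_boxstats.csv")
  )
}

model_for_record <- function(sex, bmi, overrides = list()) {
  g <- BMI_LEVELS[max(findInterval(bmi, c(18.5, 25, 30, 35, 40)), 1L)]
  model <- default_profile_model(sex, g)
  if (length(overrides) > 0) model[names(overrides)] <- overrides
  model
}

#' Simulate a study: cohort, geometries, ground-truth profiles, phantoms
#'
#' Writes `cohort.csv`, `landmarks.csv`, `slice_areas.csv` (and, for the
#' first `masks_n` participants, NIfTI phantom volumes under `masks/`)
#' plus a stage manifest into `config$out_dir`. Deterministic under a
#' fixed `config$seed`: rerunning with the same configuration produces
#' byte-identical CSV output.
#'
#' @param config A [run_config()].
#' @return Invisible list of output paths.
#' @export
simulate_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  paths <- stage_paths(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  withr::local_seed(config$seed)

  calib <- if (!is.null(config$calibration_csv)) {
    tibble::as_tibble(read.csv(config$calibration_csv, check.names = FALSE))
  } else {
    default_calibration()
  }
  cohort <- generate_participants(config$n_participants, calib = calib)
  if (sum(unlist(config$exclusions)) > 0) {
    cohort <- inject_exclusions(cohort, config$exclusions,
                                min_subgroup = config$min_subgroup)
  }
  geoms <- generate_geometries(cohort)

  grid <- anatomical_grid(config$grid$n_caudal_points)
  t_cm <- config$grid$slice_thickness_cm
  # One shared slice grid: long enough for the tallest trunk.
  tops <- vapply(geoms, function(g) g[["Th10"]], numeric(1))
  n_slices <- floor((max(tops) + 50) / (t_cm * 10)) + 1L
  profiles <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    model <- model_for_record(cohort$sex[i], cohort$bmi[i],
                              config$model_overrides)
    pr <- generate_true_profile(cohort[i, ], geoms[[i]], model,
                                slice_thickness_cm = t_cm, grid = grid)
    pad <- n_slices - length(pr$areas_cm2)
    if (pad > 0) {
      pr <- slice_profile(c(pr$areas_cm2, rep(0, pad)), thickness_cm = t_cm)
    }
    profiles[[i]] <- pr
  }
  names(profiles) <- cohort$id

  write_cohort_csv(cohort, paths$cohort)
  write_landmarks_csv(geoms, paths$landmarks)
  write_slice_areas_csv(profiles, paths$slice_areas)

  if (config$masks_n > 0) {
    dir.create(paths$masks_dir, showWarnings = FALSE)
    for (i in seq_len(min(config$masks_n, nrow(cohort)))) {
      vol <- render_mask(profiles[[i]], geoms[[i]],
                         voxel_spacing = c(1.4, 1.4, t_cm * 10))
      write_mask_nifti(
        vol,
        file.path(paths$masks_dir, paste0(cohort$id[i], "_vat.nii.gz")),
        file.path(paths$masks_dir, paste0(cohort$id[i], "_spine.nii.gz"))
      )
    }
  }
  outs <- c(paths$cohort, paths$landmarks, paths$slice_areas)
  write_manifest("simulate", config, outs,
                 file.path(config$out_dir, "simulate_manifest.json"))
  invisible(paths)
}

#' Extract standardized profiles from simulated (or measured) inputs
#'
#' Reads the per-slice area matrix and the landmark table, standardizes
#' every participant to the anatomical grid, and writes `profiles.csv`.
#' If NIfTI masks exist under `masks/`, they are used for those
#' participants instead of the area table (exercising the voxel path).
#' Participants that fail to standardize are skipped with a logged reason.
#'
#' @param config A [run_config()].
#' @return Invisible profile tibble.
#' @export
extract_profiles <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  paths <- stage_paths(config)
  for (p in c(paths$landmarks, paths$slice_areas)) {
    if (!file.exists(p)) stop("missing upstream output: ", p)
  }
  landmarks <- read_landmarks_csv(paths$landmarks)
  profiles <- read_slice_areas_csv(paths$slice_areas)
  if (dir.exists(paths$masks_dir)) {
    vat_files <- list.files(paths$masks_dir, pattern = "_vat\\.nii(\\.gz)?$",
                            full.names = TRUE)
    for (f in vat_files) {
      pid <- sub("_vat\\.nii(\\.gz)?$", "", basename(f))
      vol <- read_mask_nifti(f)
      profiles[[pid]] <- compute_slice_areas(vol$data, vol$spacing)
    }
  }
  grid <- anatomical_grid(config$grid$n_caudal_points)
  std <- standardize_cohort(profiles, landmarks, grid)
  write_profiles_csv(std, paths$profiles)
  write_manifest("extract", config, paths$profiles,
                 file.path(config$out_dir, "extract_manifest.json"))
  invisible(std)
}

#' Analyze the cohort: exclusions, stratum profiles, factor table
#'
#' Applies the exclusion cascade, computes stratum mean profiles with
#' SEMs, finds the age-independent intersection per sex x BMI group,
#' derives the scaling factors, and writes the Table-1-style cohort
#' summary, the sex-comparison t tests and the Gaussian KDE of the
#' FH-to-L5 distances.
#'
#' @param config A [run_config()].
#' @return Invisible list with `factors`, `stats`, `excl`.
#' @export
analyze_cohort <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  paths <- stage_paths(config)
  for (p in c(paths$cohort, paths$profiles)) {
    if (!file.exists(p)) stop("missing upstream output: ", p)
  }
  cohort <- read_cohort_csv(paths$cohort)
  profiles <- read_profiles_csv(paths$profiles)
  need <- c("id", "sex", "age", "bmi", "vat_total_l")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0) stop("cohort.csv lacks column(s): ", paste(miss, collapse = ", "))

  excl <- apply_exclusions(cohort, min_subgroup = config$min_subgroup)
  kept <- excl$cohort
  groups <- assign_groups_df(kept)
  profiles <- profiles[profiles$id %in% kept$id, ]

  grid <- anatomical_grid(config$grid$n_caudal_points)
  stats <- stratum_profiles(profiles, groups, grid)
  factors <- derive_factor_table(
    profiles, groups, stats,
    metric = config$toggles$spread_metric,
    method = config$toggles$factor_method,
    slice_thickness_cm = config$grid$slice_thickness_cm
  )

  summary_tbl <- dplyr::summarise(
    dplyr::group_by(dplyr::inner_join(kept, groups, by = c("id", "sex")),
                    sex, bmi_group),
    n = dplyr::n(),
    age_mean = mean(age), age_sd = sd(age),
    height_mean = mean(height_cm), height_sd = sd(height_cm),
    bmi_mean = mean(bmi), bmi_sd = sd(bmi),
    vat_mean = mean(vat_total_l), vat_sd = sd(vat_total_l),
    .groups = "drop"
  )
  men <- kept[kept$sex == "M", ]
  women <- kept[kept$sex == "F", ]
  tt_age <- two_sample_t(men$age, women$age)
  tt_bmi <- two_sample_t(men$bmi, women$bmi)
  tests <- tibble::tibble(
    comparison = c("age_men_vs_women", "bmi_men_vs_women"),
    t = c(tt_age$t, tt_bmi$t), df = c(tt_age$df, tt_bmi$df),
    p = c(tt_age$p, tt_bmi$p)
  )

  landmarks <- read_landmarks_csv(paths$landmarks)
  dist_cm <- vapply(landmarks[kept$id], function(g) {
    (g[["L5"]] - g[["FH"]]) / 10
  }, numeric(1))
  kde <- kde_distance(dist_cm)

  write_csv_plain(stats, paths$stratum_stats)
  write_factor_table(factors, paths$factors_json, paths$factors_csv)
  write_csv_plain(summary_tbl, paths$cohort_summary)
  write_csv_plain(tests, paths$tests_summary)
  write_csv_plain(kde, paths$distance_kde)
  write_csv_plain(excl$counts, file.path(config$out_dir, "exclusion_counts.csv"))
  write_manifest("analyze", config,
                 c(paths$stratum_stats, paths$factors_json, paths$factors_csv),
                 file.path(config$out_dir, "analyze_manifest.json"))
  invisible(list(factors = factors, stats = stats, excl = excl))
}

#' Estimate single-slice VAT volumes and validate them
#'
#' Applies the factor table to every retained participant, then writes
#' per-participant estimates, the per-group correlation/regression
#' summary, the sex-level error summary and the BMI x age boxplot
#' statistics.
#'
#' @param config A [run_config()].
#' @return Invisible list with `estimates`, `validation`, `errors`.
#' @export
estimate_stage <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  paths <- stage_paths(config)
  for (p in c(paths$cohort, paths$profiles, paths$factors_json)) {
    if (!file.exists(p)) stop("missing upstream output: ", p)
  }
  cohort <- read_cohort_csv(paths$cohort)
  profiles <- read_profiles_csv(paths$profiles)
  factors <- read_factor_table(paths$factors_json)
  excl <- apply_exclusions(cohort, min_subgroup = config$min_subgroup)
  groups <- assign_groups_df(excl$cohort)
  groups <- groups[groups$id %in% profiles$id, ]

  est <- estimate_cohort(profiles, groups, factors,
                         slice_thickness_cm = config$grid$slice_thickness_cm)
  corr <- validate_correlation(est$estimate_l, est$reference_l,
                               paste(est$sex, est$bmi_group))
  errs <- error_metrics(est$estimate_l, est$reference_l, est$sex,
                        method = config$toggles$relative_error)
  box <- error_boxplot_stats(est)

  write_csv_plain(est, paths$estimates)
  write_csv_plain(corr, paths$validation)
  write_csv_plain(errs, file.path(config$out_dir, "error_summary.csv"))
  write_csv_plain(box, paths$error_boxstats)
  write_manifest("estimate", config,
                 c(paths$estimates, paths$validation, paths$error_boxstats),
                 file.path(config$out_dir, "estimate_manifest.json"))
  invisible(list(estimates = est, validation = corr, errors = errs,
                 boxstats = box))
}
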