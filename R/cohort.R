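# Cohort analysis: grouping, exclusions, stratum mean profiles,
# age-intersection search, scaling factors, and the supporting statistics.

#' Assign a participant to sex, BMI group and age group
#'
#' BMI groups use half-open intervals `[18.5,25) [25,30) [30,35) [35,40)
#' [40,Inf)` (labels I-V); age groups `[20,30) ... [50,60) [60,Inf)`
#' (labels i-v; everyone 60 or older is in group v, which also absorbs the
#' few participants over 70). A BMI below 18.5 kg/m2 (underweight) or an
#' age below 20 is an exclusion error, not a group.
#'
#' @param record One-row tibble/list with `sex`, `bmi`, `age`.
#' @return List with `sex`, `bmi_group`, `age_group` (factors).
#' @export
assign_groups <- function(record) {
  bmi <- record$bmi[1]
  age <- record$age[1]
  if (is.na(bmi) || is.na(age)) stop("bmi and age must be present")
  if (bmi < 18.5) {
    stop("underweight participant (BMI < 18.5 kg/m2) is excluded, not grouped")
  }
  if (age < 20) stop("age below 20 years is outside the study range")
  list(
    sex = record$sex[1],
    bmi_group = factor(BMI_LEVELS[findInterval(bmi, c(18.5, 25, 30, 35, 40))],
                       levels = BMI_LEVELS),
    age_group = factor(AGE_LEVELS[age_decade(age)], levels = AGE_LEVELS)
  )
}

#' Vectorized group assignment for a cohort
#'
#' @param cohort Participant tibble with `id`, `sex`, `bmi`, `age`.
#' @return Tibble `id`, `sex`, `bmi_group`, `age_group`.
#' @export
assign_groups_df <- function(cohort) {
  if (any(is.na(cohort$bmi)) || any(is.na(cohort$age))) {
    stop("bmi and age must be present for all participants")
  }
  if (any(cohort$bmi < 18.5)) stop("underweight participants must be excluded first")
  if (any(cohort$age < 20)) stop("participants below 20 years are outside the study range")
  tibble::tibble(
    id = cohort$id,
    sex = cohort$sex,
    bmi_group = factor(BMI_LEVELS[findInterval(cohort$bmi, c(18.5, 25, 30, 35, 40))],
                       levels = BMI_LEVELS),
    age_group = factor(AGE_LEVELS[age_decade(cohort$age)], levels = AGE_LEVELS)
  )
}

#' Apply the exclusion cascade to a cohort
#'
#' Removal order: fat-water swaps, corrupted image data, missing
#' anthropometry, underweight (BMI < 18.5 kg/m2), then every
#' sex x BMI x age stratum with fewer than `min_subgroup` members. Counts
#' are reported per criterion in that order, so
#' `n_in - n_out = sum(counts)`.
#'
#' @param cohort Participant tibble.
#' @param min_subgroup Minimum retained stratum size (default 10).
#' @return List with `cohort` (retained rows), `counts` (tibble
#'   `criterion`, `n_removed`).
#' @export
apply_exclusions <- function(cohort, min_subgroup = 10L) {
  if (nrow(cohort) == 0) stop("cohort is empty")
  present <- rep(TRUE, nrow(cohort))
  removed <- integer(0)

  drop <- function(mask) {
    k <- sum(mask & present)
    present[mask & present] <<- FALSE
    k
  }
  removed["fat_water_swap"] <- drop(cohort$flag_fat_water_swap)
  removed["corrupted"] <- drop(cohort$flag_corrupted)
  removed["missing_anthropometry"] <- drop(
    cohort$flag_missing_anthropometry |
      is.na(cohort$height_cm) | is.na(cohort$weight_kg) | is.na(cohort$bmi)
  )
  removed["underweight"] <- drop(!is.na(cohort$bmi) & cohort$bmi < 18.5)

  rows <- which(present)
  if (length(rows) > 0) {
    grp <- assign_groups_df(cohort[rows, ])
    key <- paste(grp$sex, grp$bmi_group, grp$age_group)
    tab <- table(key)
    small <- names(tab)[tab < min_subgroup]
    mask <- rep(FALSE, nrow(cohort))
    mask[rows[key %in% small]] <- TRUE
    removed["small_subgroup"] <- drop(mask)
  } else {
    removed["small_subgroup"] <- 0L
  }
  list(
    cohort = cohort[present, , drop = FALSE],
    counts = tibble::tibble(criterion = names(removed),
                            n_removed = as.integer(removed))
  )
}

#' Stratum mean profiles with standard errors
#'
#' Per sex x BMI group x age group and grid location: stratum size, mean
#' percentage and standard error of the mean (sd / sqrt(n)).
#'
#' @param profiles Standardized profile tibble from [standardize_cohort()].
#' @param groups Group assignment tibble from [assign_groups_df()].
#' @param grid The [anatomical_grid] (fixes the location factor order).
#' @return Tibble `sex`, `bmi_group`, `age_group`, `location`, `n`,
#'   `mean_pct`, `sem`.
#' @export
stratum_profiles <- function(profiles, groups, grid = anatomical_grid()) {
  missing <- setdiff(profiles$id, groups$id)
  if (length(missing) > 0) {
    stop("profiles without a group assignment: ", length(missing), " participant(s)")
  }
  long <- tidyr::pivot_longer(profiles,
                              cols = -dplyr::all_of(c("id", "vat_total_l")),
                              names_to = "location", values_to = "pct")
  long <- dplyr::inner_join(long, groups, by = "id")
  out <- dplyr::summarise(
    dplyr::group_by(long, sex, bmi_group, age_group, location),
    n = dplyr::n(),
    mean_pct = mean(pct),
    sem = if (dplyr::n() > 1) sd(pct) / sqrt(dplyr::n()) else 0,
    .groups = "drop"
  )
  out$location <- factor(out$location, levels = grid$labels)
  dplyr::arrange(out, sex, bmi_group, age_group, location)
}

#' Find the age-independent intersection location for one stratum
#'
#' Returns the grid location where the age-group mean profiles of the
#' given sex x BMI group differ least. The spread at a location is the
#' range (max minus min) of the age-group means (`metric = "variance"` is
#' available as an alternative reading of "smallest difference between all
#' age groups"). The search is restricted to locations carrying
#' non-negligible VAT — pooled mean at least `min_pooled_frac` of the
#' stratum's maximum pooled mean — since outside the trunk's fat-bearing
#' range every age curve is trivially near zero and an "intersection"
#' there would be meaningless for estimation. Exact ties are broken toward
#' the location with the largest pooled (size-weighted) mean percentage.
#'
#' @param stats Stratum statistics from [stratum_profiles()].
#' @param sex,bmi_group Stratum selector.
#' @param metric `"range"` (default) or `"variance"`.
#' @param min_pooled_frac Search floor as a fraction of the maximum pooled
#'   mean (default 0.1; 0 disables the restriction).
#' @return Location label (character) with attributes `spread` and
#'   `pooled_mean`.
#' @export
find_intersection <- function(stats, sex, bmi_group,
                              metric = c("range", "variance"),
                              min_pooled_frac = 0.1) {
  metric <- match.arg(metric)
  sub <- stats[stats$sex == sex & stats$bmi_group == bmi_group, ]
  if (nrow(sub) == 0) stop("no data for stratum ", sex, " / ", bmi_group)
  n_age <- length(unique(sub$age_group))
  if (n_age < 2) {
    stop("intersection undefined: only one age group in stratum ",
         sex, " / ", bmi_group)
  }
  spread_fun <- if (metric == "range") {
    function(x) max(x) - min(x)
  } else {
    function(x) var(x)
  }
  per_loc <- dplyr::summarise(
    dplyr::group_by(sub, location),
    spread = spread_fun(mean_pct),
    pooled = weighted.mean(mean_pct, n),
    .groups = "drop"
  )
  per_loc <- per_loc[per_loc$pooled >= min_pooled_frac * max(per_loc$pooled), ]
  min_spread <- min(per_loc$spread)
  cand <- per_loc[per_loc$spread <= min_spread + 1e-12, ]
  best <- cand[which.max(cand$pooled), ]
  structure(as.character(best$location),
            spread = best$spread, pooled_mean = best$pooled)
}

#' Derive the single-slice scaling factor for one stratum
#'
#' The factor f converts a single-slice VAT area (cm2) at the reference
#' location into an estimated total volume: `V_hat [l] = A [cm2] * f /
#' 1000`. The default is the ratio of means, `f = 1000 * mean(V) /
#' mean(A)` over all participants of the sex x BMI group pooled across
#' age (equivalently: slice thickness in cm divided by the group-level
#' mean per-slice VAT fraction at the location, the reciprocal of the
#' single-slice percentage); `method = "mean_of_ratios"` averages the
#' per-participant ratios instead (kept for sensitivity analyses).
#'
#' @param profiles Standardized profile tibble (with `vat_total_l`).
#' @param groups Group assignment tibble.
#' @param location Grid location label.
#' @param sex,bmi_group Stratum selector.
#' @param method `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @param slice_thickness_cm Slice thickness used to convert percentages
#'   back to areas (default 0.3).
#' @return The factor (positive scalar).
#' @export
derive_factor <- function(profiles, groups, location, sex, bmi_group,
                          method = c("ratio_of_means", "mean_of_ratios"),
                          slice_thickness_cm = SLICE_THICKNESS_CM_DEFAULT) {
  method <- match.arg(method)
  if (!location %in% names(profiles)) {
    stop("location not present in profile matrix: ", location)
  }
  ids <- groups$id[groups$sex == sex & groups$bmi_group == bmi_group]
  sub <- profiles[profiles$id %in% ids, ]
  if (nrow(sub) == 0) stop("empty stratum ", sex, " / ", bmi_group)
  v_l <- sub$vat_total_l
  area <- sub[[location]] / 100 * v_l * 1000 / slice_thickness_cm
  if (method == "ratio_of_means") {
    if (mean(area) <= 0) stop("zero mean slice area at ", location)
    1000 * mean(v_l) / mean(area)
  } else {
    if (any(area <= 0)) stop("zero slice area at ", location, " for some participants")
    mean(1000 * v_l / area)
  }
}

#' Derive the full factor table (all sex x BMI groups)
#'
#' Runs [find_intersection()] and [derive_factor()] for every sex x BMI
#' group present.
#'
#' @inheritParams derive_factor
#' @param stats Stratum statistics from [stratum_profiles()].
#' @param metric Spread metric passed to [find_intersection()].
#' @return Tibble `sex`, `bmi_group`, `location`, `factor`.
#' @export
derive_factor_table <- function(profiles, groups, stats,
                                metric = c("range", "variance"),
                                method = c("ratio_of_means", "mean_of_ratios"),
                                slice_thickness_cm = SLICE_THICKNESS_CM_DEFAULT) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  strata <- unique(stats[, c("sex", "bmi_group")])
  strata <- dplyr::arrange(strata, dplyr::desc(sex == "M"), bmi_group)
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    sx <- strata$sex[i]
    bg <- as.character(strata$bmi_group[i])
    loc <- find_intersection(stats, sx, bg, metric = metric)
    f <- derive_factor(profiles, groups, as.character(loc), sx, bg,
                       method = method, slice_thickness_cm = slice_thickness_cm)
    tibble::tibble(sex = sx, bmi_group = bg,
                   location = as.character(loc), factor = f)
  })
  dplyr::bind_rows(rows)
}

#' Pooled-variance two-sample t test
#'
#' Student's two-sample t statistic with pooled variance and
#' `df = n1 + n2 - 2` (so groups of 5,681 and 5,355 give df 11,034), as
#' used for the descriptive sex comparisons of age and BMI. The degenerate
#' case of zero pooled variance with equal means returns t = 0.
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  df <- length(a) + length(b) - 2
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0))
  }
  res <- t.test(a, b, var.equal = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter), p = res$p.value)
}

#' Gaussian kernel density estimate of landmark distances
#'
#' Gaussian kernel with Silverman's rule-of-thumb bandwidth, used to
#' describe the distribution of measured femoral-head-to-L5 distances.
#' The estimate integrates to one on its evaluation grid.
#'
#' @param distances Numeric vector (cm), at least two distinct values.
#' @param n Number of evaluation points (default 512).
#' @return Tibble `x`, `y` with attribute `bandwidth`.
#' @export
kde_distance <- function(distances, n = 512) {
  distances <- distances[is.finite(distances)]
  if (length(unique(distances)) < 2) {
    stop("need at least two distinct distances (zero bandwidth otherwise)")
  }
  d <- density(distances, bw = "nrd0", kernel = "gaussian", n = n)
  structure(tibble::tibble(x = d$x, y = d$y), bandwidth = d$bw)
}
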