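# Synthetic cohort generator: participants, spine geometries, craniocaudal
# VAT profiles with planted age-intersection structure, and voxelized
# phantom masks. All downstream stages are exercised on these inputs.

BMI_GROUP_LO <- c(I = 18.5, II = 25, III = 30, IV = 35, V = 40)
BMI_GROUP_HI <- c(I = 25, II = 30, III = 35, IV = 40, V = Inf)
AGE_BIN_LO <- c(i = 20, ii = 30, iii = 40, iv = 50, v = 60)
AGE_BIN_HI <- c(i = 30, ii = 40, iii = 50, iv = 60, v = 73)

# Cohort-mean body height (cm) used to scale vertebral spacing.
REFERENCE_HEIGHT_CM <- 171.7

#' Default cohort calibration table
#'
#' Per sex and BMI group: subgroup size and mean/sd of age, height, weight,
#' BMI and total VAT volume, matching the descriptive statistics of the
#' population MRI cohort the generator emulates (5,681 men and 5,355 women
#' after exclusions; men's VAT averaging about 73 % above women's in every
#' BMI group).
#'
#' @return A tibble with one row per sex x BMI group.
#' @export
default_calibration <- function() {
  men <- tibble::tibble(
    sex = "M",
    bmi_group = factor(BMI_LEVELS, levels = BMI_LEVELS),
    n = c(1690L, 2733L, 979L, 234L, 45L),
    age_mean = c(48.4, 53.3, 54.4, 55.4, 54.0),
    age_sd = c(12.3, 10.8, 10.3, 9.2, 8.2),
    height_mean = c(179.0, 178.1, 177.6, 176.9, 175.3),
    height_sd = c(6.9, 6.9, 7.0, 7.1, 8.3),
    weight_mean = c(74.1, 86.6, 101.1, 115.7, 130.8),
    weight_sd = c(7.2, 7.8, 8.6, 10.5, 16.2),
    bmi_mean = c(23.1, 27.3, 32.0, 36.9, 42.4),
    bmi_sd = c(1.4, 1.4, 1.4, 1.3, 2.3),
    vat_mean = c(2.8, 5.0, 7.0, 8.7, 9.7),
    vat_sd = c(1.3, 1.7, 1.8, 2.1, 2.2)
  )
  women <- tibble::tibble(
    sex = "F",
    bmi_group = factor(BMI_LEVELS, levels = BMI_LEVELS),
    n = c(2577L, 1676L, 743L, 260L, 99L),
    age_mean = c(49.4, 53.5, 55.0, 56.0, 54.7),
    age_sd = c(11.7, 10.7, 10.2, 9.6, 7.3),
    height_mean = c(166.0, 164.4, 163.4, 163.1, 162.3),
    height_sd = c(6.5, 6.5, 6.3, 6.4, 6.8),
    weight_mean = c(61.4, 73.5, 85.8, 98.6, 115.6),
    weight_sd = c(6.4, 6.8, 7.4, 8.5, 11.8),
    bmi_mean = c(22.3, 27.2, 32.1, 37.0, 43.8),
    bmi_sd = c(1.6, 1.4, 1.4, 1.4, 3.2),
    vat_mean = c(1.5, 2.8, 4.1, 5.1, 5.8),
    vat_sd = c(0.8, 1.1, 1.3, 1.3, 1.4)
  )
  dplyr::bind_rows(men, women)
}

validate_calibration <- function(calib) {
  need <- c("sex", "bmi_group", "n", "age_mean", "age_sd", "height_mean",
            "height_sd", "bmi_mean", "bmi_sd", "vat_mean", "vat_sd")
  missing <- setdiff(need, names(calib))
  if (length(missing) > 0) {
    stop("calibration table lacks column(s): ", paste(missing, collapse = ", "))
  }
  key <- paste(calib$sex, calib$bmi_group)
  want <- paste(rep(c("M", "F"), each = 5), rep(BMI_LEVELS, 2))
  if (!all(want %in% key)) {
    stop("calibration must cover both sexes and all five BMI groups")
  }
  sds <- unlist(calib[c("age_sd", "height_sd", "bmi_sd", "vat_sd")])
  if (any(sds <= 0) || any(calib$n <= 0)) {
    stop("calibration sds must be positive and group sizes nonempty")
  }
  invisible(calib)
}

# Truncated-normal draws via the probability-integral transform (exact,
# vectorized, no rejection loop).
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

age_decade <- function(age) {
  pmin(pmax(findInterval(age, AGE_BIN_LO), 1L), 5L)
}

#' Generate synthetic participants
#'
#' Draws participants whose sex ratio, BMI-group proportions and covariate
#' moments converge to a calibration table as `n` grows. Within each
#' sex x BMI group, BMI is truncated normal within the group's interval,
#' height is truncated normal, weight is derived from BMI and height (so
#' the BMI identity holds exactly), age is drawn by discretizing the
#' group's age distribution onto the five 10-year bins and sampling
#' uniformly within the bin, and total VAT is log-normal with moments
#' matched to the group mean/sd (VAT is positive and right-skewed).
#'
#' @param n Number of participants (>= 1).
#' @param seed Optional integer seed (RNG state is restored on exit).
#' @param calib Calibration table, see [default_calibration()].
#' @return Tibble with columns `id`, `sex`, `age`, `height_cm`,
#'   `weight_kg`, `bmi`, the three exclusion flags (all `FALSE`) and
#'   `vat_total_l` (ground-truth volume).
#' @export
generate_participants <- function(n, seed = NULL, calib = default_calibration()) {
  if (n < 1) stop("n must be >= 1")
  validate_calibration(calib)
  if (!is.null(seed)) withr::local_seed(seed)

  stratum <- sample.int(nrow(calib), n, replace = TRUE, prob = calib$n)
  out <- tibble::tibble(
    id = sprintf("P%06d", seq_len(n)),
    sex = character(n), age = integer(n), height_cm = numeric(n),
    weight_kg = numeric(n), bmi = numeric(n),
    flag_fat_water_swap = FALSE, flag_corrupted = FALSE,
    flag_missing_anthropometry = FALSE,
    vat_total_l = numeric(n)
  )
  for (g in seq_len(nrow(calib))) {
    idx <- which(stratum == g)
    if (length(idx) == 0) next
    d <- .draw_covariates(calib[g, ], length(idx))
    out$sex[idx] <- d$sex
    out$age[idx] <- d$age
    out$height_cm[idx] <- d$height_cm
    out$bmi[idx] <- d$bmi
    out$weight_kg[idx] <- d$weight_kg
    out$vat_total_l[idx] <- d$vat_total_l
  }
  out
}

# Covariate draws for k participants of one calibration row.
.draw_covariates <- function(row, k) {
  grp <- as.character(row$bmi_group)
  bmi_hi <- min(BMI_GROUP_HI[[grp]], row$bmi_mean + 3.5 * row$bmi_sd)
  bmi <- rtrunc_norm(k, row$bmi_mean, row$bmi_sd, BMI_GROUP_LO[[grp]], bmi_hi)
  height <- rtrunc_norm(k, row$height_mean, row$height_sd,
                        row$height_mean - 4 * row$height_sd,
                        row$height_mean + 4 * row$height_sd)
  # Age: discretize Normal(mean, sd) onto the decade bins, then uniform
  # integer age within the bin (60-72 for the open top bin).
  pbin <- pnorm(AGE_BIN_HI, row$age_mean, row$age_sd) -
    pnorm(AGE_BIN_LO, row$age_mean, row$age_sd)
  pbin <- pbin / sum(pbin)
  bin <- sample.int(5L, k, replace = TRUE, prob = pbin)
  age <- AGE_BIN_LO[bin] + floor(runif(k) * (AGE_BIN_HI[bin] - AGE_BIN_LO[bin]))
  cv <- row$vat_sd / row$vat_mean
  sdlog <- sqrt(log1p(cv^2))
  meanlog <- log(row$vat_mean) - sdlog^2 / 2
  list(sex = row$sex, age = as.integer(age), height_cm = height, bmi = bmi,
       weight_kg = bmi * (height / 100)^2,
       vat_total_l = rlnorm(k, meanlog, sdlog))
}

#' Generate a cohort restricted to one sex x BMI stratum
#'
#' Draws covariates from a single calibration row, optionally forcing a
#' balanced age design (useful for planted-structure recovery
#' experiments).
#'
#' @param sex,bmi_group Stratum selector.
#' @param n Number of participants.
#' @param ages Optional integer vector recycled over participants (e.g.
#'   `c(25, 35, 45, 55, 65)` for a balanced 5-age-group design).
#' @param seed Optional integer seed.
#' @param calib Calibration table.
#' @return Participant tibble as from [generate_participants()].
#' @export
generate_stratum_cohort <- function(sex, bmi_group, n, ages = NULL,
                                    seed = NULL,
                                    calib = default_calibration()) {
  validate_calibration(calib)
  if (!is.null(seed)) withr::local_seed(seed)
  row <- calib[calib$sex == sex & calib$bmi_group == bmi_group, ]
  if (nrow(row) != 1) stop("no calibration row for ", sex, " / ", bmi_group)
  d <- .draw_covariates(row, n)
  out <- tibble::tibble(
    id = sprintf("P%06d", seq_len(n)),
    sex = d$sex, age = d$age, height_cm = d$height_cm,
    weight_kg = d$weight_kg, bmi = d$bmi,
    flag_fat_water_swap = FALSE, flag_corrupted = FALSE,
    flag_missing_anthropometry = FALSE,
    vat_total_l = d$vat_total_l
  )
  if (!is.null(ages)) out$age <- as.integer(rep_len(ages, n))
  out
}

# Typical lumbar/lower-thoracic center-to-center spacings (mm) at the
# reference height; scaled linearly with body height.
VERTEBRAL_SPACING_MM <- c(35, 36, 35, 34, 32, 28, 26) # L5-L4 ... Th11-Th10

.generate_geometry_core <- function(height_cm,
                                    distance_mean = 12.9,
                                    distance_sd = 1.1,
                                    distance_range = c(9, 17),
                                    fh_position_mm = 9,
                                    spacing_jitter = 0.02) {
  d_cm <- rtrunc_norm(1, distance_mean, distance_sd,
                      distance_range[1], distance_range[2])
  scale <- height_cm / REFERENCE_HEIGHT_CM
  jitter <- if (spacing_jitter > 0) exp(rnorm(7, 0, spacing_jitter)) else rep(1, 7)
  spacing <- VERTEBRAL_SPACING_MM * scale * jitter
  l5 <- fh_position_mm + 10 * d_cm
  centers <- l5 + cumsum(c(0, spacing)) # L5, L4, ..., Th10
  names(centers) <- c("L5", "L4", "L3", "L2", "L1", "Th12", "Th11", "Th10")
  discs <- (centers[-8] + centers[-1]) / 2
  names(discs) <- c("L5/4", "L4/3", "L3/2", "L2/1", "L1/Th12", "Th12/11", "Th11/10")
  spine_landmarks(c(FH = fh_position_mm, centers, discs))
}

#' Generate a spine geometry for one participant
#'
#' Landmark positions increase strictly caudal to cranial. The distance
#' from the L5 center to the femoral-head center is drawn from
#' Normal(12.9, 1.1) cm truncated to 9-17 cm (truncation avoids
#' non-physical geometries at extreme draws); vertebral spacing scales
#' linearly with body height with a small log-normal jitter.
#'
#' @param record One-row participant tibble (or list) with `height_cm`.
#' @param seed Optional integer seed.
#' @param distance_mean,distance_sd,distance_range Parameters (cm) of the
#'   truncated normal FH-L5 distance distribution.
#' @param fh_position_mm Axial position of the femoral-head center.
#' @param spacing_jitter Log-sd of per-level spacing jitter (0 disables).
#' @return A [spine_landmarks] object.
#' @export
generate_geometry <- function(record, seed = NULL,
                              distance_mean = 12.9, distance_sd = 1.1,
                              distance_range = c(9, 17),
                              fh_position_mm = 9, spacing_jitter = 0.02) {
  if (is.null(record$height_cm) || !is.finite(record$height_cm[1]) ||
      record$height_cm[1] <= 0) {
    stop("record must carry a positive height_cm")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  .generate_geometry_core(record$height_cm[1], distance_mean, distance_sd,
                          distance_range, fh_position_mm, spacing_jitter)
}

#' Generate spine geometries for a whole cohort
#'
#' @param records Participant tibble.
#' @param seed Optional integer seed (one stream for the whole cohort).
#' @inheritParams generate_geometry
#' @return Named list of [spine_landmarks], one per participant id.
#' @export
generate_geometries <- function(records, seed = NULL,
                                distance_mean = 12.9, distance_sd = 1.1,
                                distance_range = c(9, 17),
                                fh_position_mm = 9, spacing_jitter = 0.02) {
  if (!is.null(seed)) withr::local_seed(seed)
  out <- lapply(records$height_cm, .generate_geometry_core,
                distance_mean = distance_mean, distance_sd = distance_sd,
                distance_range = distance_range,
                fh_position_mm = fh_position_mm,
                spacing_jitter = spacing_jitter)
  names(out) <- records$id
  out
}

#' Default craniocaudal profile model for a sex and BMI group
#'
#' The continuous VAT density (fraction of total VAT per cm) is the sum of
#' a pelvic plateau (logistic shoulder ending `boundary_offset_cm` below
#' L5, the pelvic/abdominal boundary) and a Gaussian abdominal component
#' centered at `abdominal_peak_location`. Defaults emulate the qualitative
#' cohort findings: the abdominal peak sits at L3 in men for every BMI
#' group and shifts from L5/4 toward L3 with increasing BMI in women; the
#' pelvic level is higher in women; the abdominal peak grows and the pelvic
#' plateau shrinks with BMI. Younger age groups carry relatively more
#' pelvic VAT, a trend that reverses across the age range
#' (`age_slope_pelvic` < 0 is the fraction of total VAT the profile loses
#' from the pelvic direction per decade of age). The age effect is a
#' sum-zero redistribution between a deep-pelvic shoulder (ending
#' `deep_fraction` of the way from the femoral heads to the
#' pelvic/abdominal boundary) and the base profile, balanced per
#' individual so that the standardized value at
#' `planted_intersection` is exactly age-independent; the implied
#' abdominal change has the opposite sign to the pelvic one. Setting
#' `age_slope_abdominal` explicitly replaces this with a plain
#' mixing-ratio age effect (no planted crossing).
#'
#' @param sex `"M"` or `"F"`.
#' @param bmi_group BMI group label `"I"`..`"V"`.
#' @return A `profile_model` list.
#' @export
default_profile_model <- function(sex, bmi_group) {
  sex <- match.arg(sex, c("M", "F"))
  g <- match(match.arg(bmi_group, BMI_LEVELS), BMI_LEVELS)
  if (sex == "M") {
    peak <- "L3"
    a <- c(0.045, 0.050, 0.055, 0.060, 0.062)[g]
    p <- c(0.030, 0.027, 0.024, 0.021, 0.019)[g]
    planted <- c("L5/4", "L5-1 cm", "L5-2.5 cm", "L2/1", "L5-7 cm")[g]
  } else {
    peak <- c("L5/4", "L4", "L4/3", "L3", "L3")[g]
    a <- c(0.046, 0.050, 0.054, 0.058, 0.060)[g]
    p <- c(0.026, 0.025, 0.024, 0.023, 0.022)[g]
    planted <- c("L5", "L5-2.5 cm", "L1", "L2/1", "L1")[g]
  }
  structure(
    list(
      pelvic_plateau = p,
      abdominal_peak_height = a,
      abdominal_peak_location = peak,
      boundary_offset_cm = 3,
      shoulder_width_cm = 1.2,
      abdominal_sigma_cm = if (sex == "M") 5 else 4,
      background = 0.002,
      deep_fraction = 0.5,
      deep_fraction_jitter = 0.08,
      abdominal_broaden = 1.3,
      age_curvature = 0.015,
      age_slope_pelvic = -0.04,
      age_slope_abdominal = NULL,
      planted_intersection = planted,
      noise_sd = 0.012,
      coverage_above_th10_cm = 5
    ),
    class = "profile_model"
  )
}

validate_profile_model <- function(model) {
  if (!is.list(model)) stop("model must be a profile_model list")
  num <- c("pelvic_plateau", "abdominal_peak_height", "boundary_offset_cm",
           "shoulder_width_cm", "abdominal_sigma_cm", "deep_fraction",
           "abdominal_broaden", "age_curvature", "background", "noise_sd")
  for (f in num) {
    v <- model[[f]]
    if (is.null(v) || !is.finite(v)) stop("model field ", f, " missing or non-finite")
  }
  if (model$pelvic_plateau < 0 || model$abdominal_peak_height < 0) {
    stop("plateau and peak heights must be >= 0")
  }
  if (model$shoulder_width_cm <= 0 || model$abdominal_sigma_cm <= 0) {
    stop("shape widths must be positive")
  }
  if (model$noise_sd < 0) stop("noise_sd must be >= 0")
  invisible(model)
}

# Pelvic (u), abdominal (v) and deep-pelvic (w) component shapes on the
# slice grid, plus the sum-zero age-redistribution direction h that
# vanishes at the planted intersection under the standardization rule.
# Because h sums to zero and is zero at the planted location, adding any
# multiple of it leaves both the normalization and the standardized value
# there unchanged: every age-group curve crosses at the planted location
# exactly.
profile_components <- function(geometry, model,
                               slice_thickness_cm = SLICE_THICKNESS_CM_DEFAULT,
                               grid = anatomical_grid()) {
  validate_profile_model(model)
  dz <- slice_thickness_cm * 10
  top_mm <- geometry[["Th10"]] + model$coverage_above_th10_cm * 10
  n_slices <- floor(top_mm / dz) + 1L
  z_mm <- (seq_len(n_slices) - 1L) * dz
  zc <- z_mm / 10
  fh <- geometry[["FH"]] / 10
  b <- geometry[["L5"]] / 10 - model$boundary_offset_cm
  covered <- zc >= fh - 1e-9
  u <- ifelse(covered, 1 / (1 + exp((zc - b) / model$shoulder_width_cm)), 0)
  pos_all <- grid_location_positions(grid, geometry)
  mu <- pos_all[[model$abdominal_peak_location]] / 10
  v <- ifelse(covered, exp(-(zc - mu)^2 / (2 * model$abdominal_sigma_cm^2)), 0)
  # Deep-pelvic shoulder ends a fixed fraction of the way from the femoral
  # heads to the pelvic/abdominal boundary, so its mass scales with the
  # individual's pelvic extent.
  b_w <- fh + model$deep_fraction * (b - fh)
  w <- ifelse(covered, 1 / (1 + exp((zc - b_w) / model$shoulder_width_cm)), 0)

  # Per-slice fraction shapes (each sums to one over the covered trunk).
  un <- u / sum(u)
  vn <- v / sum(v)
  wn <- w / sum(w)
  # A small uniform background (mediastinal/retroperitoneal fat present on
  # every covered slice) keeps the tails strictly positive.
  base_p <- model$pelvic_plateau * u + model$abdominal_peak_height * v +
    model$background * covered
  base_p <- base_p / sum(base_p)

  h <- NULL
  h2 <- NULL
  if (!is.null(model$planted_intersection)) {
    lab <- model$planted_intersection
    if (!lab %in% grid$labels) stop("planted_intersection not a grid label: ", lab)
    z_star <- pos_all[[lab]]
    type <- grid$type[match(lab, grid$labels)]
    at_star <- function(x) {
      if (type == "landmark") x[which.min(abs(z_mm - z_star))]
      else approx(z_mm, x, xout = z_star)$y
    }
    # Sum-zero age directions, each made to vanish at the planted
    # location by a sum-zero pair of concentric Gaussian bumps centered
    # there (well-conditioned for any location: the narrow minus the wide
    # bump is bounded away from zero at the center). h is a
    # pelvic/abdominal redistribution (linear in age); h2 an abdominal
    # broadening (quadratic in age). Because the two age weights are
    # linearly independent across the five age groups, the only location
    # where every age-group curve agrees exactly is the planted one.
    g1 <- ifelse(covered, exp(-(zc - z_star / 10)^2 / 2), 0)       # sigma 1 cm
    g2 <- ifelse(covered, exp(-(zc - z_star / 10)^2 / (2 * 9)), 0) # sigma 3 cm
    cshape <- g1 / sum(g1) - g2 / sum(g2)
    c_star <- at_star(cshape)
    if (!is.finite(c_star) || abs(c_star) < 1e-6) {
      stop("cannot plant an age intersection at ", lab,
           " for this geometry (location at the edge of coverage)")
    }
    pin <- function(x) x - (at_star(x) / c_star) * cshape
    h <- pin(wn - base_p)
    vw <- ifelse(covered,
                 exp(-(zc - mu)^2 /
                       (2 * (model$abdominal_broaden * model$abdominal_sigma_cm)^2)),
                 0)
    h2 <- pin(vw / sum(vw) - vn)
  }
  list(z_mm = z_mm, base_p = base_p, un = un, vn = vn, wn = wn,
       h = h, h2 = h2,
       s_u = sum(u), s_v = sum(v), positions = pos_all)
}

#' Generate the ground-truth per-slice VAT profile for one participant
#'
#' Evaluates the two-component density on the slice grid, adds the
#' participant's age effect (`-age_slope_pelvic * (decade - 3)` times the
#' sum-zero redistribution direction that vanishes at the planted
#' intersection, see [default_profile_model()]), optionally adds per-slice
#' Gaussian noise (renormalizing the slice fractions to sum to one over
#' the covered trunk), and scales to the participant's ground-truth total
#' VAT so that the sum of slice area times thickness reproduces
#' `vat_total_l` exactly.
#'
#' @param record One-row participant tibble with `age` and `vat_total_l`.
#' @param geometry A [spine_landmarks] object.
#' @param model A `profile_model`, see [default_profile_model()].
#' @param seed Optional integer seed (noise only).
#' @param slice_thickness_cm Axial slice thickness (default 0.3 cm).
#' @param grid The [anatomical_grid] used to resolve the planted labels.
#' @return A `slice_profile`, see [slice_profile()].
#' @export
generate_true_profile <- function(record, geometry, model, seed = NULL,
                                  slice_thickness_cm = SLICE_THICKNESS_CM_DEFAULT,
                                  grid = anatomical_grid()) {
  if (!is.null(seed)) withr::local_seed(seed)
  # Per-individual shape heterogeneity: the deep-pelvic extent varies
  # between subjects. The planted crossing holds for any deep fraction
  # (h vanishes at the planted location by construction), but the
  # incidental second zero of the redistribution direction moves, so no
  # other grid location is exactly age-independent at the stratum level.
  jit <- model$deep_fraction_jitter %||% 0
  if (jit > 0) {
    model$deep_fraction <- model$deep_fraction + runif(1, -jit, jit)
  }
  comp <- profile_components(geometry, model, slice_thickness_cm, grid)
  dec <- age_decade(record$age[1])
  delta <- model$age_slope_pelvic * (dec - 3) # negative slope: young (dec 1) -> more pelvic
  if (!is.null(model$age_slope_abdominal)) {
    # Explicit slopes: plain mixing-ratio change (natural crossing).
    c_p <- 1 + model$age_slope_pelvic * (dec - 3)
    c_a <- 1 + model$age_slope_abdominal * (dec - 3)
    if (c_p <= 0 || c_a <= 0) {
      stop("age slopes too large: component weight would be non-positive")
    }
    q <- model$pelvic_plateau * c_p * comp$s_u * comp$un +
      model$abdominal_peak_height * c_a * comp$s_v * comp$vn
    p <- q / sum(q)
  } else if (!is.null(comp$h)) {
    eps <- model$age_curvature * ((dec - 3)^2 - 2)
    q <- delta * comp$h + eps * comp$h2
    # Scale the age effect down per individual if it would drive any
    # slice fraction negative (short-pelvis geometries concentrate the
    # deep-pelvic shape). The planted crossing is preserved for any
    # magnitude because both directions vanish there.
    neg <- q < 0
    if (any(neg)) {
      s <- min(comp$base_p[neg] / (-q[neg]), 1)
      if (s < 0.5) {
        stop("age redistribution too strong: per-slice fraction would be negative")
      }
      if (s < 1) q <- q * 0.98 * s
    }
    p <- comp$base_p + q
  } else {
    p <- comp$base_p
  }
  if (model$noise_sd > 0) {
    # Between-subject variation scales with the local VAT level: additive
    # Gaussian noise with sd proportional to the slice fraction, equal to
    # noise_sd (fraction per cm) at the profile peak.
    sd_i <- model$noise_sd * slice_thickness_cm * p / max(p)
    p <- pmax(p + rnorm(length(p), 0, 1) * sd_i, 0)
    p <- p / sum(p)
  }
  vat_l <- record$vat_total_l[1]
  if (!is.finite(vat_l) || vat_l < 0) stop("record must carry vat_total_l >= 0")
  areas <- p * vat_l * 1000 / slice_thickness_cm
  out <- slice_profile(areas, positions_mm = comp$z_mm,
                       thickness_cm = slice_thickness_cm)
  attr(out, "components") <- list(delta = delta, h = comp$h,
                                  base_p = comp$base_p)
  out
}

#' Render a VAT mask and spine label volume from a per-slice area sequence
#'
#' Each axial slice receives a single filled ellipse whose voxel count
#' matches the requested area to within half a voxel (voxels are ranked
#' once by elliptical radius from the in-plane center, and the closest
#' `round(area / voxel_area)` voxels are filled, so all slices share one
#' concentric ellipse family). Spine landmarks become 2x2-voxel blocks,
#' label ids 1..16 in caudal-to-cranial [LANDMARK_LABELS] order, placed at
#' the axial slice nearest each landmark position.
#'
#' @param areas Numeric per-slice areas (cm2) or a `slice_profile`.
#' @param geometry A [spine_landmarks] object.
#' @param voxel_spacing (dx, dy, dz) in mm; default `c(1.4, 1.4, 3)`.
#' @param seed Accepted for interface symmetry; rendering is deterministic.
#' @param dims_xy In-plane matrix size.
#' @param aspect Ellipse aspect ratio (x semi-axis over y semi-axis).
#' @return List with integer arrays `vat` and `spine`, `spacing`, and a
#'   `label_map` tibble.
#' @export
render_mask <- function(areas, geometry, voxel_spacing = c(1.4, 1.4, 3),
                        seed = NULL, dims_xy = c(320L, 260L), aspect = 1.5) {
  if (inherits(areas, "slice_profile")) areas <- areas$areas_cm2
  if (any(!is.finite(areas)) || any(areas < 0)) {
    stop("areas must be finite and >= 0")
  }
  if (any(voxel_spacing <= 0)) stop("voxel spacing must be positive")
  dx <- voxel_spacing[1]; dy <- voxel_spacing[2]; dz <- voxel_spacing[3]
  nx <- dims_xy[1]; ny <- dims_xy[2]; nz <- length(areas)
  vox_area <- dx * dy / 100 # cm2

  a_max <- sqrt(max(areas) * aspect / pi) # cm, semi-major (x)
  b_max <- sqrt(max(areas) / (aspect * pi))
  if (2 * a_max * 10 > (nx - 4) * dx || 2 * b_max * 10 > (ny - 4) * dy) {
    stop("requested area exceeds the slice field of view")
  }

  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  xs <- (seq_len(nx) - cx) * dx
  ys <- (seq_len(ny) - cy) * dy
  r2 <- outer(xs^2 / aspect, ys^2 * aspect, "+") # elliptical radius^2, shared
  ord <- order(as.vector(r2))

  counts <- round(areas / vox_area)
  vat <- array(0L, dim = c(nx, ny, nz))
  plane <- nx * ny
  for (s in seq_len(nz)) {
    if (counts[s] > 0) {
      vat[ord[seq_len(counts[s])] + (s - 1L) * plane] <- 1L
    }
  }

  spine <- array(0L, dim = c(nx, ny, nz))
  xi <- round(cx) + c(0L, 1L)
  yi <- round(0.85 * ny) + c(0L, 1L)
  for (k in seq_along(LANDMARK_LABELS)) {
    zi <- round(geometry[[LANDMARK_LABELS[k]]] / dz) + 1L
    if (zi < 1L || zi > nz) {
      stop("landmark ", LANDMARK_LABELS[k], " falls outside the rendered volume")
    }
    spine[xi, yi, zi] <- k
  }
  list(vat = vat, spine = spine, spacing = voxel_spacing,
       label_map = tibble::tibble(label_id = seq_along(LANDMARK_LABELS),
                                  label = LANDMARK_LABELS))
}

#' Plant exclusion structure into a synthetic cohort
#'
#' Sets exactly the requested number of each exclusion flag on disjoint
#' participants, optionally rewrites `underweight` participants to a BMI
#' below 18.5 kg/m2, and optionally plants `small_stratum` participants
#' into sex x BMI x age cells of size below 10 (after relocating natural
#' members of small or targeted cells into the largest cell of their
#' sex x BMI group) so that the downstream subgroup-size filter removes an
#' exact, known count.
#'
#' @param cohort Participant tibble from [generate_participants()].
#' @param counts Named vector/list with any of `fat_water_swap`,
#'   `corrupted`, `missing_anthropometry`, `underweight`, `small_stratum`.
#' @param seed Optional integer seed.
#' @param min_subgroup Subgroup threshold the planted cells must stay
#'   under (default 10; planted cells hold at most `min_subgroup - 1`).
#' @return The modified cohort.
#' @export
inject_exclusions <- function(cohort, counts, seed = NULL, min_subgroup = 10L) {
  allowed <- c("fat_water_swap", "corrupted", "missing_anthropometry",
               "underweight", "small_stratum")
  counts <- unlist(counts)
  bad <- setdiff(names(counts), allowed)
  if (length(bad) > 0) stop("unknown exclusion count(s): ", paste(bad, collapse = ", "))
  full <- setNames(rep(0L, length(allowed)), allowed)
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0) || sum(full) > nrow(cohort)) {
    stop("exclusion counts must be >= 0 and sum to at most the cohort size")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  n <- nrow(cohort)
  avail <- seq_len(n)
  take <- function(k) {
    idx <- if (k > 0) sort(sample(avail, k)) else integer(0)
    avail <<- setdiff(avail, idx)
    idx
  }
  cohort$flag_fat_water_swap[take(full[["fat_water_swap"]])] <- TRUE
  cohort$flag_corrupted[take(full[["corrupted"]])] <- TRUE
  cohort$flag_missing_anthropometry[take(full[["missing_anthropometry"]])] <- TRUE

  uw <- take(full[["underweight"]])
  if (length(uw) > 0) {
    cohort$bmi[uw] <- runif(length(uw), 17, 18.4)
    cohort$weight_kg[uw] <- cohort$bmi[uw] * (cohort$height_cm[uw] / 100)^2
  }

  k_small <- full[["small_stratum"]]
  if (k_small > 0) {
    cohort <- .plant_small_strata(cohort, k_small, min_subgroup)
  }
  cohort
}

# Internal: make the subgroup-size filter remove exactly k participants.
.plant_small_strata <- function(cohort, k, min_subgroup) {
  chunk_max <- min_subgroup - 1L
  targets <- list(
    c("M", "V", "i"), c("F", "V", "i"), c("M", "IV", "i"),
    c("F", "IV", "i"), c("M", "III", "i"), c("F", "III", "i")
  )
  if (k > chunk_max * length(targets)) {
    stop("small_stratum count too large to plant (max ",
         chunk_max * length(targets), ")")
  }
  eligible <- function() {
    !cohort$flag_fat_water_swap & !cohort$flag_corrupted &
      !cohort$flag_missing_anthropometry & cohort$bmi >= 18.5
  }
  cell_of <- function(rows) {
    bg <- BMI_LEVELS[findInterval(cohort$bmi[rows], c(18.5, 25, 30, 35, 40))]
    ag <- AGE_LEVELS[age_decade(cohort$age[rows])]
    paste(cohort$sex[rows], bg, ag)
  }
  n_chunks <- ceiling(k / chunk_max)
  target_keys <- vapply(targets[seq_len(n_chunks)], paste, collapse = " ", "")

  # Relocate members of targeted or naturally small cells into the largest
  # cell of the same sex x BMI group (by resampling the age within that
  # cell's decade); iterate until stable.
  for (pass in 1:10) {
    rows <- which(eligible())
    keys <- cell_of(rows)
    tab <- table(keys)
    small <- names(tab)[tab > 0 & tab < min_subgroup]
    evict <- union(intersect(names(tab), target_keys), small)
    if (length(evict) == 0) break
    moved <- FALSE
    for (key in evict) {
      parts <- strsplit(key, " ", fixed = TRUE)[[1]]
      grp_keys <- paste(parts[1], parts[2], AGE_LEVELS)
      sizes <- tab[match(grp_keys, names(tab))]
      sizes[is.na(sizes)] <- 0
      sizes[grp_keys %in% target_keys] <- -1 # never evict into a target
      dest <- which.max(sizes)
      if (grp_keys[dest] == key) next # already the biggest; leave for filter
      members <- rows[keys == key]
      lo <- AGE_BIN_LO[dest]; hi <- AGE_BIN_HI[dest]
      cohort$age[members] <- as.integer(lo + floor(runif(length(members)) * (hi - lo)))
      moved <- TRUE
    }
    if (!moved) break
  }

  # Donors come from large cells; rewrite them into the target cells.
  rows <- which(eligible())
  keys <- cell_of(rows)
  tab <- sort(table(keys), decreasing = TRUE)
  donor_pool <- rows[keys %in% names(tab)[1:2]]
  if (length(donor_pool) < k) stop("not enough donors to plant small strata")
  donors <- sample(donor_pool, k)
  bmi_mid <- c(I = 21.7, II = 27.5, III = 32.5, IV = 37.5, V = 41.5)
  left <- k
  ci <- 1L
  for (d in donors) {
    tgt <- targets[[ci]]
    cohort$sex[d] <- tgt[1]
    cohort$bmi[d] <- bmi_mid[[tgt[2]]]
    cohort$height_cm[d] <- if (tgt[1] == "M") 178 else 165
    cohort$weight_kg[d] <- cohort$bmi[d] * (cohort$height_cm[d] / 100)^2
    cohort$age[d] <- 24L
    left <- left - 1L
    if ((k - left) %% chunk_max == 0L) ci <- ci + 1L
  }
  cohort
}
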