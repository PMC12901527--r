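# Shared fixture builders: everything is generated in code at test time.

# Standardize a whole cohort of generated profiles to the grid, returning
# the wide profile tibble the analysis functions consume.
build_profile_matrix <- function(cohort, geoms, grid = anatomical_grid(),
                                 model_override = NULL) {
  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    model <- if (is.null(model_override)) {
      default_profile_model(cohort$sex[i],
                            cut(cohort$bmi[i], c(18.5, 25, 30, 35, 40, Inf),
                                labels = BMI_LEVELS, right = FALSE))
    } else {
      model_override
    }
    pr <- generate_true_profile(cohort[i, ], geoms[[i]], model, grid = grid)
    rows[[i]] <- standardize_profile(pr, geoms[[i]], grid)
  }
  mat <- do.call(rbind, rows)
  dplyr::bind_cols(
    tibble::tibble(id = cohort$id, vat_total_l = cohort$vat_total_l),
    tibble::as_tibble(as.data.frame(mat, check.names = FALSE))
  )
}

# One-stratum experiment: generate, standardize, locate the intersection
# and derive the factor. Used by planted-structure recovery tests.
run_stratum_experiment <- function(sex, bmi_group, n_per_age, noise = NULL,
                                   seed = 1) {
  set.seed(seed)
  cohort <- generate_stratum_cohort(sex, bmi_group, n_per_age * 5,
                                    ages = c(25L, 35L, 45L, 55L, 65L))
  geoms <- generate_geometries(cohort)
  model <- default_profile_model(sex, bmi_group)
  if (!is.null(noise)) model$noise_sd <- noise
  grid <- anatomical_grid()
  profiles <- build_profile_matrix(cohort, geoms, grid, model_override = model)
  groups <- assign_groups_df(cohort)
  stats <- stratum_profiles(profiles, groups, grid)
  loc <- find_intersection(stats, sex, bmi_group)
  list(cohort = cohort, geoms = geoms, model = model, profiles = profiles,
       groups = groups, stats = stats, location = as.character(loc))
}

# A deterministic hand-built geometry with landmarks on exact slice
# centers (3 mm spacing), convenient for exactness tests.
toy_landmarks <- function(scale = 1) {
  base <- c(FH = 9, L5 = 135, L4 = 171, L3 = 207, L2 = 240, L1 = 273,
            Th12 = 303, Th11 = 330, Th10 = 357)
  base <- base * scale
  discs <- (base[2:8] + base[3:9]) / 2
  names(discs) <- c("L5/4", "L4/3", "L3/2", "L2/1", "L1/Th12", "Th12/11",
                    "Th11/10")
  spine_landmarks(c(base, discs))
}
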