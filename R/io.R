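# File handling: deterministic CSV/JSON writers, NIfTI volumes, run
# configuration and stage manifests.

#' Build and validate a run configuration
#'
#' Configuration keys (all optional; defaults shown by
#' `run_config()`): `seed`, `n_participants`, `masks_n` (how many
#' participants additionally get voxelized NIfTI phantoms), `out_dir`,
#' `grid` (`n_caudal_points`, `slice_thickness_cm`), `exclusions`
#' (planted counts: `fat_water_swap`, `corrupted`, `missing_anthropometry`,
#' `underweight`, `small_stratum`), `min_subgroup`, `toggles`
#' (`spread_metric` range/variance, `factor_method`
#' ratio_of_means/mean_of_ratios, `relative_error` abs_of_mean/mean_of_abs),
#' `model_overrides` (named profile-model fields applied to every stratum,
#' e.g. `noise_sd`), `calibration_csv` (path to an alternative calibration
#' table). Unknown keys are rejected.
#'
#' @param x Named list of overrides.
#' @param file Optional YAML file read before applying `x`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(x = list(), file = NULL) {
  defaults <- list(
    seed = 1L,
    n_participants = 2000L,
    masks_n = 0L,
    out_dir = "results",
    grid = list(n_caudal_points = 26L, slice_thickness_cm = 0.3),
    exclusions = list(fat_water_swap = 0L, corrupted = 0L,
                      missing_anthropometry = 0L, underweight = 0L,
                      small_stratum = 0L),
    min_subgroup = 10L,
    toggles = list(spread_metric = "range",
                   factor_method = "ratio_of_means",
                   relative_error = "abs_of_mean"),
    model_overrides = list(),
    calibration_csv = NULL
  )
  if (!is.null(file)) {
    from_file <- yaml::read_yaml(file)
    x <- modifyList(from_file, x)
  }
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (nested in c("grid", "exclusions", "toggles")) {
    extra <- setdiff(names(x[[nested]]), names(defaults[[nested]]))
    if (length(extra) > 0) {
      stop("unknown config key(s) under ", nested, ": ",
           paste(extra, collapse = ", "))
    }
  }
  cfg <- modifyList(defaults, x)
  if (cfg$n_participants < 1) stop("n_participants must be >= 1")
  if (cfg$masks_n < 0) stop("masks_n must be >= 0")
  if (cfg$grid$n_caudal_points < 2) stop("grid$n_caudal_points must be >= 2")
  if (cfg$grid$slice_thickness_cm <= 0) stop("slice_thickness_cm must be positive")
  if (cfg$min_subgroup < 1) stop("min_subgroup must be >= 1")
  cfg$toggles$spread_metric <- match.arg(cfg$toggles$spread_metric,
                                         c("range", "variance"))
  cfg$toggles$factor_method <- match.arg(cfg$toggles$factor_method,
                                         c("ratio_of_means", "mean_of_ratios"))
  cfg$toggles$relative_error <- match.arg(cfg$toggles$relative_error,
                                          c("abs_of_mean", "mean_of_abs"))
  structure(cfg, class = "run_config")
}

#' Hash of a configuration (for manifests)
#' @param config A `run_config`.
#' @return MD5 string of the canonical YAML serialization.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(md5sum(tmp))
}

write_manifest <- function(stage, config, outputs, path) {
  jsonlite::write_json(
    list(stage = stage,
         package = "vatslice",
         version = as.character(utils::packageVersion("vatslice")),
         config_hash = config_hash(config),
         outputs = outputs),
    path, auto_unbox = TRUE, pretty = TRUE
  )
}

# Deterministic CSV (UTF-8, comma separator, "." decimal, header row).
write_csv_plain <- function(x, path) {
  write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8", quote = FALSE)
}

#' Cohort table I/O
#'
#' Columns: `id`, `sex`, `age`, `height_cm`, `weight_kg`, `bmi`, the three
#' `flag_*` columns, `vat_total_l`.
#' @param cohort Participant tibble.
#' @param path CSV path.
#' @export
write_cohort_csv <- function(cohort, path) write_csv_plain(cohort, path)

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  x <- tibble::as_tibble(read.csv(path, check.names = FALSE))
  for (f in grep("^flag_", names(x), value = TRUE)) x[[f]] <- as.logical(x[[f]])
  x
}

#' Landmark table I/O (long format: id, label, position_mm)
#' @param landmarks Named list of [spine_landmarks].
#' @param path CSV path.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  long <- dplyr::bind_rows(lapply(names(landmarks), function(i) {
    tibble::tibble(id = i, label = names(landmarks[[i]]),
                   position_mm = as.numeric(landmarks[[i]]))
  }))
  write_csv_plain(long, path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  long <- read.csv(path, check.names = FALSE)
  out <- lapply(split(long, long$id), function(d) {
    spine_landmarks(setNames(d$position_mm, d$label))
  })
  out[unique(long$id)]
}

#' Per-slice area matrix I/O (one row per participant, slice columns)
#'
#' Column names encode the slice-center position (`z<mm>`), so the axial
#' coordinate survives the round trip.
#' @param profiles Named list of [slice_profile] objects.
#' @param path CSV path.
#' @export
write_slice_areas_csv <- function(profiles, path) {
  pos <- profiles[[1]]$positions_mm
  t_cm <- profiles[[1]]$thickness_cm
  mat <- do.call(rbind, lapply(profiles, function(p) {
    if (length(p$areas_cm2) != length(pos)) {
      stop("all slice profiles must share one slice grid")
    }
    p$areas_cm2
  }))
  df <- data.frame(id = names(profiles), thickness_cm = t_cm, mat,
                   check.names = FALSE)
  names(df)[-(1:2)] <- sprintf("z%g", pos)
  write_csv_plain(df, path)
}

#' @rdname write_slice_areas_csv
#' @export
read_slice_areas_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  zcols <- grep("^z", names(df), value = TRUE)
  pos <- as.numeric(sub("^z", "", zcols))
  out <- lapply(seq_len(nrow(df)), function(i) {
    slice_profile(as.numeric(df[i, zcols]), positions_mm = pos,
                  thickness_cm = df$thickness_cm[i])
  })
  names(out) <- df$id
  out
}

#' Standardized profile matrix I/O
#'
#' One row per participant; 40 location columns in percent plus
#' `vat_total_l`.
#' @param profiles Profile tibble from [standardize_cohort()].
#' @param path CSV path.
#' @export
write_profiles_csv <- function(profiles, path) write_csv_plain(profiles, path)

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  tibble::as_tibble(read.csv(path, check.names = FALSE))
}

#' Factor table I/O
#'
#' JSON layout: sex -> BMI group -> `{location, factor}`; the CSV mirror
#' has one row per sex x BMI group.
#' @param factors Factor tibble from [derive_factor_table()].
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @export
write_factor_table <- function(factors, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    nested <- lapply(split(factors, factors$sex), function(d) {
      out <- lapply(seq_len(nrow(d)), function(i) {
        list(location = d$location[i], factor = d$factor[i])
      })
      names(out) <- as.character(d$bmi_group)
      out
    })
    jsonlite::write_json(nested, json_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) write_csv_plain(factors, csv_path)
  invisible(factors)
}

#' @rdname write_factor_table
#' @param path JSON path to read back.
#' @export
read_factor_table <- function(path) {
  nested <- jsonlite::read_json(path)
  dplyr::bind_rows(lapply(names(nested), function(sx) {
    dplyr::bind_rows(lapply(names(nested[[sx]]), function(bg) {
      tibble::tibble(sex = sx, bmi_group = bg,
                     location = nested[[sx]][[bg]]$location,
                     factor = as.numeric(nested[[sx]][[bg]]$factor))
    }))
  }))
}

#' Write a rendered phantom as NIfTI volumes
#'
#' The voxel spacing is stored in the NIfTI header (`pixdim`).
#' @param vol List from [render_mask()].
#' @param vat_path,spine_path Output paths (`.nii` or `.nii.gz`).
#' @export
write_mask_nifti <- function(vol, vat_path, spine_path = NULL) {
  img <- RNifti::asNifti(vol$vat)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, vat_path)
  if (!is.null(spine_path)) {
    simg <- RNifti::asNifti(vol$spine)
    RNifti::pixdim(simg) <- vol$spacing
    RNifti::writeNifti(simg, spine_path)
  }
  invisible(vat_path)
}

#' Read a NIfTI mask volume with its voxel spacing
#' @param path NIfTI file path.
#' @return List with `data` (array) and `spacing` (mm triple).
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.integer(img), dim = dim(img)),
       spacing = RNifti::pixdim(img)[1:3])
}
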