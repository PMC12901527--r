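# Profile extraction: per-slice VAT areas from masks, landmark centroids
# from spine label volumes, and standardization to the anatomical grid.

#' Per-slice VAT profile
#'
#' Container for a craniocaudal sequence of axial VAT cross-sectional
#' areas. Slice positions are in mm from the most caudal acquired slice
#' (0-based slice index times the slice thickness), increasing caudal to
#' cranial. Fractions are per-slice shares of total VAT over the covered
#' trunk and sum to one; they are `NA` (flagged undefined) for an empty
#' profile.
#'
#' @param areas_cm2 Numeric per-slice areas in cm2 (finite, >= 0).
#' @param positions_mm Slice-center positions; defaults to
#'   `(0:(n-1)) * thickness_cm * 10`.
#' @param thickness_cm Slice thickness in cm (default 0.3).
#' @return A `slice_profile` list with `areas_cm2`, `positions_mm`,
#'   `thickness_cm`, `vat_total_l`, `fractions`.
#' @export
slice_profile <- function(areas_cm2, positions_mm = NULL,
                          thickness_cm = SLICE_THICKNESS_CM_DEFAULT) {
  if (any(!is.finite(areas_cm2)) || any(areas_cm2 < 0)) {
    stop("areas must be finite and >= 0")
  }
  if (is.null(positions_mm)) {
    positions_mm <- (seq_along(areas_cm2) - 1) * thickness_cm * 10
  }
  stopifnot(length(positions_mm) == length(areas_cm2))
  total <- sum(areas_cm2)
  vat_l <- total * thickness_cm / 1000
  fractions <- if (total > 0) areas_cm2 / total else rep(NA_real_, length(areas_cm2))
  structure(
    list(areas_cm2 = as.numeric(areas_cm2),
         positions_mm = as.numeric(positions_mm),
         thickness_cm = thickness_cm,
         vat_total_l = vat_l,
         fractions = fractions),
    class = "slice_profile"
  )
}

#' Compute per-slice VAT areas from a binary mask
#'
#' `area_i = (voxel count in slice i) * dx * dy / 100` cm2. At the default
#' acquisition spacing of 1.4 x 1.4 x 3 mm, 100 voxels in a slice give
#' 1.96 cm2. An empty mask yields a valid profile with zero total volume
#' and undefined (NA) fractions.
#'
#' @param mask 3D binary array (0/1), third dimension axial, slice 1 most
#'   caudal.
#' @param spacing (dx, dy, dz) in mm.
#' @return A [slice_profile].
#' @export
compute_slice_areas <- function(mask, spacing = c(1.4, 1.4, 3)) {
  if (length(dim(mask)) != 3) stop("mask must be a 3D array")
  if (any(spacing <= 0)) stop("voxel spacing must be positive")
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1))) stop("mask must be binary (0/1)")
  counts <- apply(mask, 3, sum)
  areas <- counts * spacing[1] * spacing[2] / 100
  slice_profile(areas, thickness_cm = spacing[3] / 10)
}

#' Locate spine landmarks from a labeled volume
#'
#' Each landmark position is the centroid axial coordinate (mm) of its
#' label. Labels follow [LANDMARK_LABELS] order (ids 1..16) unless a
#' `label_map` reassigns them. A missing label, or centroids violating the
#' caudal-to-cranial ordering (signalling a corrupted segmentation), is an
#' error.
#'
#' @param spine_labels 3D integer array of label ids (0 background).
#' @param spacing (dx, dy, dz) in mm.
#' @param label_map Optional tibble with `label_id`, `label`.
#' @return A [spine_landmarks] object.
#' @export
locate_landmarks <- function(spine_labels, spacing = c(1.4, 1.4, 3),
                             label_map = NULL) {
  if (length(dim(spine_labels)) != 3) stop("spine_labels must be a 3D array")
  if (is.null(label_map)) {
    label_map <- tibble::tibble(label_id = seq_along(LANDMARK_LABELS),
                                label = LANDMARK_LABELS)
  }
  nz <- dim(spine_labels)[3]
  per_slice <- apply(spine_labels, 3, function(sl) {
    tabulate(sl[sl > 0], nbins = max(label_map$label_id))
  })
  if (is.null(dim(per_slice))) per_slice <- matrix(per_slice, nrow = 1)
  z_mm <- (seq_len(nz) - 1) * spacing[3]
  pos <- vapply(seq_len(nrow(label_map)), function(i) {
    counts <- per_slice[label_map$label_id[i], ]
    tot <- sum(counts)
    if (tot == 0) {
      stop("label missing from spine volume: ", label_map$label[i])
    }
    sum(counts * z_mm) / tot
  }, numeric(1))
  names(pos) <- label_map$label
  spine_landmarks(pos)
}

#' Standardize a per-slice profile to the anatomical grid
#'
#' Produces the per-location percentage of total VAT per slice. Values at
#' the vertebral-body and disc locations come from the axial slice nearest
#' the landmark (no sub-slice interpolation; at 3 mm slices the difference
#' is negligible). Values at the caudal locations come from linear
#' interpolation of the per-slice VAT amounts at the individual's
#' `n_caudal_points` equidistant positions between the femoral heads and
#' L5. Indexing by anatomical label rather than absolute position removes
#' the direct influence of body height.
#'
#' @param profile A [slice_profile].
#' @param landmarks A [spine_landmarks] object.
#' @param grid An [anatomical_grid].
#' @return Named numeric vector (length `length(grid$labels)`) of
#'   percentages, with attributes `vat_total_l` and `undefined` (TRUE for
#'   an empty profile, where all values are NA).
#' @export
standardize_profile <- function(profile, landmarks, grid = anatomical_grid()) {
  stopifnot(inherits(profile, "slice_profile"),
            inherits(landmarks, "spine_landmarks"))
  z <- profile$positions_mm
  lo <- min(z) - profile$thickness_cm * 10 / 2
  hi <- max(z) + profile$thickness_cm * 10 / 2
  outside <- LANDMARK_LABELS[landmarks < lo | landmarks > hi]
  if (length(outside) > 0) {
    stop("landmark(s) outside profile coverage: ",
         paste(outside, collapse = ", "))
  }
  total <- sum(profile$areas_cm2)
  vals <- rep(NA_real_, length(grid$labels))
  names(vals) <- grid$labels
  if (total == 0) {
    warning("empty profile: standardized values undefined")
    return(structure(vals, vat_total_l = 0, undefined = TRUE))
  }
  caudal_pos <- build_caudal_scale(landmarks, grid$n_caudal_points)
  caudal_vals <- approx(z, profile$areas_cm2, xout = caudal_pos)$y / total
  land_pos <- as.numeric(landmarks[VERTEBRAL_GRID_LABELS])
  nearest <- vapply(land_pos, function(p) which.min(abs(z - p)), integer(1))
  land_vals <- profile$areas_cm2[nearest] / total
  vals[] <- 100 * c(caudal_vals, land_vals)
  structure(vals, vat_total_l = profile$vat_total_l, undefined = FALSE)
}

#' Standardize a whole cohort of profiles
#'
#' @param profiles Named list of [slice_profile] objects (names = ids) or
#'   a function-free list in the same order as `landmarks`.
#' @param landmarks Named list of [spine_landmarks] (same names).
#' @param grid An [anatomical_grid].
#' @return Tibble: `id`, `vat_total_l`, one column per grid location (%).
#'   Participants whose standardization fails are dropped with a warning.
#' @export
standardize_cohort <- function(profiles, landmarks, grid = anatomical_grid()) {
  ids <- names(profiles)
  stopifnot(!is.null(ids), all(ids %in% names(landmarks)))
  rows <- vector("list", length(ids))
  keep <- logical(length(ids))
  vat <- numeric(length(ids))
  for (i in seq_along(ids)) {
    res <- tryCatch(
      standardize_profile(profiles[[i]], landmarks[[ids[i]]], grid),
      error = function(e) e, warning = function(w) w
    )
    if (inherits(res, "condition")) {
      message("skipping ", ids[i], ": ", conditionMessage(res))
      next
    }
    rows[[i]] <- res
    vat[i] <- attr(res, "vat_total_l")
    keep[i] <- TRUE
  }
  if (!any(keep)) stop("no profile could be standardized")
  mat <- do.call(rbind, rows[keep])
  out <- tibble::as_tibble(as.data.frame(mat, check.names = FALSE))
  dplyr::bind_cols(tibble::tibble(id = ids[keep], vat_total_l = vat[keep]), out)
}
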