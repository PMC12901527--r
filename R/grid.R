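# Anatomical reference frame: spine landmarks and the standardized grid.

#' Landmark and grid label vocabularies
#'
#' `LANDMARK_LABELS` lists the 16 spine landmarks in caudal-to-cranial
#' order: the femoral-head center (FH), the vertebral-body centers L5 to
#' Th10 and the seven intervening disc centers. `BMI_LEVELS` and
#' `AGE_LEVELS` are the stratification labels (BMI groups I-V at the 18.5,
#' 25, 30, 35, 40 kg/m2 boundaries; 10-year age groups i-v starting at 20
#' years, with everyone over 60 in group v).
#'
#' @format Character vectors.
#' @export
LANDMARK_LABELS <- c(
  "FH", "L5", "L5/4", "L4", "L4/3", "L3", "L3/2", "L2", "L2/1", "L1",
  "L1/Th12", "Th12", "Th12/11", "Th11", "Th11/10", "Th10"
)

#' @rdname LANDMARK_LABELS
#' @export
BMI_LEVELS <- c("I", "II", "III", "IV", "V")

#' @rdname LANDMARK_LABELS
#' @export
AGE_LEVELS <- c("i", "ii", "iii", "iv", "v")

# Vertebral/disc grid labels above (and excluding) L5, caudal -> cranial.
VERTEBRAL_GRID_LABELS <- LANDMARK_LABELS[3:16]

SLICE_THICKNESS_CM_DEFAULT <- 0.3

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_cm <- function(x) {
  vapply(x, function(v) format(v, trim = TRUE, scientific = FALSE), character(1))
}

#' Construct a validated set of spine landmarks
#'
#' @param positions Named numeric vector of axial positions in mm (from the
#'   most caudal acquired slice, increasing caudal to cranial), containing
#'   every label in [LANDMARK_LABELS].
#' @return A `spine_landmarks` object (named numeric vector).
#' @export
spine_landmarks <- function(positions) {
  missing <- setdiff(LANDMARK_LABELS, names(positions))
  if (length(missing) > 0) {
    stop("missing landmark label(s): ", paste(missing, collapse = ", "))
  }
  pos <- as.numeric(positions[LANDMARK_LABELS])
  names(pos) <- LANDMARK_LABELS
  if (any(!is.finite(pos))) stop("non-finite landmark position")
  if (any(diff(pos) <= 0)) {
    bad <- LANDMARK_LABELS[which(diff(pos) <= 0) + 1L]
    stop("landmark positions must strictly increase caudal to cranial; ",
         "violated at: ", paste(bad, collapse = ", "))
  }
  structure(pos, class = "spine_landmarks")
}

#' Equidistant caudal scale from the femoral heads to L5
#'
#' Generates `n_points` equidistant axial positions from the femoral-head
#' center to the center of L5 (both inclusive). With the cohort-mean
#' FH-to-L5 distance of 12.9 cm and 26 points the step is 0.516 cm, i.e.
#' 0.5 cm at one-decimal rounding.
#'
#' @param landmarks A [spine_landmarks] object.
#' @param n_points Number of points including both endpoints (>= 2).
#' @return Numeric vector of positions in mm, most caudal first.
#' @export
build_caudal_scale <- function(landmarks, n_points = 26L) {
  stopifnot(inherits(landmarks, "spine_landmarks"))
  if (n_points < 2) stop("n_points must be >= 2")
  fh <- landmarks[["FH"]]
  l5 <- landmarks[["L5"]]
  if (fh >= l5) stop("femoral-head position must be caudal of L5")
  seq(fh, l5, length.out = n_points)
}

#' The standardized anatomical grid
#'
#' The 40-location grid on which craniocaudal VAT profiles are compared
#' across individuals: `n_caudal_points` equidistant locations from the
#' femoral heads to L5 (labelled by their cohort-level distance below L5,
#' e.g. `"L5-2.5 cm"`, with `"L5"` itself the most cranial of them),
#' followed by the 14 vertebral-body and disc-center locations L5/4 through
#' Th10. Caudal locations are evaluated by linear interpolation at each
#' individual's own equidistant positions; vertebral/disc locations take
#' the axial slice nearest the landmark.
#'
#' @param n_caudal_points Number of equidistant caudal points (default 26).
#' @param label_step_cm Cohort-level step size used only for labelling
#'   (default 0.5 cm).
#' @return An `anatomical_grid` object with elements `labels`, `type`
#'   (`"caudal"` or `"landmark"`), `n_caudal_points`, `label_step_cm`.
#' @export
anatomical_grid <- function(n_caudal_points = 26L, label_step_cm = 0.5) {
  if (n_caudal_points < 2) stop("n_caudal_points must be >= 2")
  k <- seq(n_caudal_points - 1L, 1L)
  caudal <- c(sprintf("L5-%s cm", fmt_cm(k * label_step_cm)), "L5")
  labels <- c(caudal, VERTEBRAL_GRID_LABELS)
  structure(
    list(
      labels = labels,
      type = c(rep("caudal", n_caudal_points),
               rep("landmark", length(VERTEBRAL_GRID_LABELS))),
      n_caudal_points = as.integer(n_caudal_points),
      label_step_cm = label_step_cm
    ),
    class = "anatomical_grid"
  )
}

#' Axial positions of every grid location for one individual
#'
#' @param grid An [anatomical_grid].
#' @param landmarks A [spine_landmarks] object.
#' @return Named numeric vector (mm) in grid order.
#' @export
grid_location_positions <- function(grid, landmarks) {
  stopifnot(inherits(grid, "anatomical_grid"))
  caudal <- build_caudal_scale(landmarks, grid$n_caudal_points)
  pos <- c(caudal, as.numeric(landmarks[VERTEBRAL_GRID_LABELS]))
  names(pos) <- grid$labels
  pos
}

#' @export
print.spine_landmarks <- function(x, ...) {
  cat("Spine landmarks (mm, caudal -> cranial):\n")
  print(round(unclass(x), 1))
  invisible(x)
}
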