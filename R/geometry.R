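# From contour stacks to morphology scalars: ACSA profile, muscle length,
# integrated volume, peak ACSA location and the shape factor.

#' Absolute area of a simple polygon
#'
#' Shoelace (surveyor's) formula; orientation-independent.
#'
#' @param vertices Numeric matrix with columns (x, y), millimetres; at least
#'   three vertices of a simple polygon. A repeated closing vertex is
#'   tolerated.
#' @return Area in mm^2.
#' @export
polygon_area <- function(vertices) {
  v <- as.matrix(vertices)
  if (nrow(v) >= 2L && all(v[1L, ] == v[nrow(v), ])) {
    v <- v[-nrow(v), , drop = FALSE]
  }
  if (nrow(v) < 3L) stop("polygon needs at least 3 vertices", call. = FALSE)
  a <- abs(signed_area(v))
  if (a < .Machine$double.eps * 100) {
    stop("degenerate polygon: area is zero (collinear vertices?)", call. = FALSE)
  }
  a
}

#' Anatomical cross-sectional area profile of a muscle
#'
#' Computes the per-slice ACSA of a contour stack: the sum of outer polygon
#' areas minus hole areas on each slice. Multiple outer contours per slice
#' (a split muscle belly) are summed.
#'
#' @param stack A validated [contour_stack()].
#' @return An object of class `acsa_profile`: list with `z` (mm, strictly
#'   increasing), `acsa` (mm^2), and the stack's `shank_landmarks`,
#'   `subject_id`, `muscle_label`.
#' @export
acsa_profile <- function(stack) {
  if (!inherits(stack, "contour_stack")) {
    stop("`stack` must be a contour_stack", call. = FALSE)
  }
  z_all <- vapply(stack$contours, function(ct) ct$z, numeric(1))
  roles <- vapply(stack$contours, function(ct) ct$role, character(1))
  areas <- vapply(stack$contours, function(ct) abs(signed_area(ct$vertices)),
                  numeric(1))
  signed <- ifelse(roles == "outer", areas, -areas)
  acsa <- vapply(stack$slice_positions, function(zi) sum(signed[z_all == zi]),
                 numeric(1))
  bad <- acsa < 0
  if (any(bad)) {
    stop(sprintf("hole area exceeds outer area on slice z = %g mm",
                 stack$slice_positions[which(bad)[1L]]), call. = FALSE)
  }
  structure(list(z = stack$slice_positions, acsa = acsa,
                 shank_landmarks = stack$shank_landmarks,
                 subject_id = stack$subject_id,
                 muscle_label = stack$muscle_label),
            class = "acsa_profile")
}

#' Muscle length from an ACSA profile
#'
#' The axial distance between the two marginal segmented slices.
#'
#' @param profile An [acsa_profile()].
#' @return Length in cm.
#' @export
muscle_length <- function(profile) {
  stopifnot(inherits(profile, "acsa_profile"))
  if (length(profile$z) < 2L) {
    stop("muscle length needs at least 2 slices", call. = FALSE)
  }
  (max(profile$z) - min(profile$z)) / 10
}

#' Measured muscle volume by slice-wise integration
#'
#' Composite trapezoidal integral of the ACSA profile along z. Exact for
#' constant and piecewise-linear profiles; accepts non-uniform slice grids.
#'
#' @param profile An [acsa_profile()].
#' @return Volume in cm^3.
#' @export
integrate_volume <- function(profile) {
  stopifnot(inherits(profile, "acsa_profile"))
  if (length(profile$z) < 2L) {
    stop("volume integration needs at least 2 slices", call. = FALSE)
  }
  pracma::trapz(profile$z, profile$acsa) / 1000  # mm^3 -> cm^3
}

#' Maximal ACSA and its position along the shank
#'
#' Returns the maximum sampled ACSA (no smoothing or sub-slice
#' interpolation) and its axial position expressed as a percentage of shank
#' length measured from the calcaneal tuberosity. Ties resolve to the most
#' distal tied slice.
#'
#' @param profile An [acsa_profile()] whose stack carried shank landmarks.
#' @return List with `ACSA_max` (cm^2), `position_pct_shank` (0-100) and
#'   `z_peak` (mm).
#' @export
find_acsa_max <- function(profile) {
  stopifnot(inherits(profile, "acsa_profile"))
  lm <- profile$shank_landmarks
  if (is.null(lm)) {
    stop("shank landmarks are required to locate the maximal ACSA", call. = FALSE)
  }
  i <- which.max(profile$acsa)  # first maximum = most distal (z ascending)
  z_peak <- profile$z[i]
  pos <- 100 * (z_peak - lm["z_distal"]) / (lm["z_proximal"] - lm["z_distal"])
  list(ACSA_max = profile$acsa[i] / 100,  # mm^2 -> cm^2
       position_pct_shank = unname(pos),
       z_peak = z_peak)
}

#' Measure the full morphology of one muscle
#'
#' Composition of the slice-wise pipeline: ACSA profile, muscle length,
#' integrated volume, maximal ACSA with shank-relative position, and the
#' shape factor p = V / (ACSA_max x L).
#'
#' @param stack A [contour_stack()] with shank landmarks.
#' @param validate Re-validate the stack before measuring (default `FALSE`;
#'   readers validate on ingestion and generators construct valid stacks).
#' @return One-row data frame with columns `subject_id`, `muscle_label`,
#'   `L_muscle_cm`, `ACSA_max_cm2`, `acsa_max_position_pct_shank`,
#'   `V_measured_cm3`, `shape_factor`.
#' @export
measure_morphology <- function(stack, validate = FALSE) {
  if (validate) validate_contour_stack(stack)
  prof <- acsa_profile(stack)
  L <- muscle_length(prof)
  V <- integrate_volume(prof)
  pk <- find_acsa_max(prof)
  p <- shape_factor(V, pk$ACSA_max, L)
  out <- data.frame(subject_id = stack$subject_id,
                    muscle_label = stack$muscle_label,
                    L_muscle_cm = L,
                    ACSA_max_cm2 = pk$ACSA_max,
                    acsa_max_position_pct_shank = pk$position_pct_shank,
                    V_measured_cm3 = V,
                    shape_factor = p,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Measure morphology for a list of contour stacks
#'
#' @param stacks List of [contour_stack()] objects (e.g. a synthetic cohort).
#' @param validate Passed to [measure_morphology()].
#' @return Data frame with one row per stack.
#' @export
measure_cohort <- function(stacks, validate = FALSE) {
  if (!length(stacks)) stop("`stacks` must be non-empty", call. = FALSE)
  do.call(rbind, lapply(stacks, measure_morphology, validate = validate))
}
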