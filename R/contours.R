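# Canonical in-memory representation of slice-wise segmentation data.
#
# Coordinate convention: right-handed frame, z along the shank axis in
# millimetres, increasing distal -> proximal. The shank reference frame runs
# from the calcaneal tuberosity (0%) to the tibial plateau (100%). All
# internal coordinates are millimetres; reported morphology uses cm/cm2/cm3.

#' Create a single slice contour
#'
#' A contour is one closed planar polygon outlining a muscle boundary on a
#' transverse slice at axial position `z`. Vertex winding is normalized to
#' counter-clockwise; the closing vertex must not be repeated.
#'
#' @param z Axial slice position, millimetres along the shank axis.
#' @param vertices Numeric matrix with two columns (x, y) in millimetres and
#'   at least three rows; the polygon is implicitly closed.
#' @param role Either `"outer"` (muscle boundary) or `"hole"` (excluded
#'   interior region such as a vessel or aponeurosis).
#' @param validate Check simplicity and non-degeneracy (default `TRUE`).
#'   Generators that construct provably valid polygons may skip the check.
#' @return An object of class `muscle_contour`.
#' @export
contour <- function(z, vertices, role = c("outer", "hole"), validate = TRUE) {
  role <- match.arg(role)
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L) {
    stop("`vertices` must be a numeric matrix with columns (x, y)", call. = FALSE)
  }
  if (nrow(vertices) >= 2L &&
      all(vertices[1L, ] == vertices[nrow(vertices), ])) {
    vertices <- vertices[-nrow(vertices), , drop = FALSE]  # drop closing vertex
  }
  if (nrow(vertices) < 3L) {
    stop(sprintf("contour at z = %g mm has fewer than 3 vertices", z),
         call. = FALSE)
  }
  if (validate) {
    if (abs(signed_area(vertices)) < .Machine$double.eps * 100) {
      stop(sprintf("degenerate (zero-area) polygon at z = %g mm", z),
           call. = FALSE)
    }
    if (!is_simple_polygon(vertices)) {
      stop(sprintf("self-intersecting polygon at z = %g mm", z), call. = FALSE)
    }
  }
  if (signed_area(vertices) < 0) {
    vertices <- vertices[rev(seq_len(nrow(vertices))), , drop = FALSE]
  }
  dimnames(vertices) <- NULL
  structure(list(z = as.numeric(z), vertices = vertices, role = role),
            class = "muscle_contour")
}

#' Assemble a contour stack for one muscle
#'
#' A contour stack holds the ordered per-slice polygons of a single muscle of
#' one subject, together with the shank landmarks used to express axial
#' positions as a percentage of shank length.
#'
#' @param contours List of [contour()] objects.
#' @param subject_id Subject identifier (character).
#' @param muscle_label Muscle name; conventionally one of `"SOL"`, `"GM"`,
#'   `"GL"` but free text is accepted.
#' @param shank_landmarks Numeric vector `c(z_distal, z_proximal)`: axial
#'   positions (mm) of the calcaneal tuberosity and the tibial plateau.
#' @param validate Run full stack validation (default `TRUE`).
#' @return An object of class `contour_stack` with elements `subject_id`,
#'   `muscle_label`, `shank_landmarks`, `contours` (sorted by z) and
#'   `slice_positions` (strictly increasing unique z values).
#' @export
contour_stack <- function(contours, subject_id = "subject",
                          muscle_label = "muscle",
                          shank_landmarks = NULL, validate = TRUE) {
  if (!length(contours)) stop("`contours` must be non-empty", call. = FALSE)
  ok <- vapply(contours, inherits, logical(1), "muscle_contour")
  if (!all(ok)) stop("all elements of `contours` must be muscle_contour objects",
                     call. = FALSE)
  z <- vapply(contours, function(ct) ct$z, numeric(1))
  contours <- contours[order(z)]
  slice_positions <- sort(unique(z))
  if (!is.null(shank_landmarks)) {
    shank_landmarks <- as.numeric(shank_landmarks)
    if (length(shank_landmarks) != 2L) {
      stop("`shank_landmarks` must be c(z_distal, z_proximal)", call. = FALSE)
    }
    names(shank_landmarks) <- c("z_distal", "z_proximal")
  }
  stack <- structure(
    list(subject_id = as.character(subject_id),
         muscle_label = as.character(muscle_label),
         shank_landmarks = shank_landmarks,
         contours = contours,
         slice_positions = slice_positions),
    class = "contour_stack")
  if (validate) validate_contour_stack(stack)
  stack
}

#' Validate a contour stack
#'
#' Checks the structural invariants: strictly increasing slice positions,
#' every contour on a declared slice, landmarks ordered distal < proximal,
#' slices within the shank extent (with tolerance), and every hole contour
#' lying inside an outer contour of the same slice.
#'
#' @param stack A `contour_stack`.
#' @param tolerance Allowed overhang (mm) of muscle slices beyond the shank
#'   landmarks; default 10 mm.
#' @return Invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
validate_contour_stack <- function(stack, tolerance = 10) {
  if (!inherits(stack, "contour_stack")) {
    stop("`stack` must be a contour_stack", call. = FALSE)
  }
  sp <- stack$slice_positions
  if (any(diff(sp) <= 0)) {
    stop("slice positions must be strictly increasing", call. = FALSE)
  }
  z <- vapply(stack$contours, function(ct) ct$z, numeric(1))
  if (!all(z %in% sp)) {
    stop("every contour's z must equal one slice position", call. = FALSE)
  }
  lm <- stack$shank_landmarks
  if (!is.null(lm)) {
    if (lm["z_proximal"] <= lm["z_distal"]) {
      stop("shank landmarks must satisfy z_proximal > z_distal", call. = FALSE)
    }
    if (min(sp) < lm["z_distal"] - tolerance ||
        max(sp) > lm["z_proximal"] + tolerance) {
      stop("muscle slices extend beyond the shank landmarks", call. = FALSE)
    }
  }
  for (zi in sp) {
    on_slice <- stack$contours[z == zi]
    roles <- vapply(on_slice, function(ct) ct$role, character(1))
    if (any(roles == "hole")) {
      outers <- on_slice[roles == "outer"]
      if (!length(outers)) {
        stop(sprintf("hole without outer contour on slice z = %g mm", zi),
             call. = FALSE)
      }
      for (h in on_slice[roles == "hole"]) {
        inside <- vapply(outers, function(o) {
          all(points_in_polygon(h$vertices, o$vertices))
        }, logical(1))
        if (!any(inside)) {
          stop(sprintf("hole not contained in any outer contour on slice z = %g mm", zi),
               call. = FALSE)
        }
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.contour_stack <- function(x, ...) {
  cat(sprintf("<contour_stack> subject %s, muscle %s\n", x$subject_id,
              x$muscle_label))
  cat(sprintf("  %d contours on %d slices, z in [%.1f, %.1f] mm\n",
              length(x$contours), length(x$slice_positions),
              min(x$slice_positions), max(x$slice_positions)))
  if (!is.null(x$shank_landmarks)) {
    cat(sprintf("  shank: %.1f mm (calcaneal tuberosity) to %.1f mm (tibial plateau)\n",
                x$shank_landmarks["z_distal"], x$shank_landmarks["z_proximal"]))
  }
  invisible(x)
}

# ---- polygon primitives (internal) ----

# Signed shoelace area; positive for counter-clockwise winding.
signed_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# Simplicity check: no two non-adjacent edges intersect. O(n^2) segment
# tests; adequate for segmentation contours (tens to hundreds of vertices).
is_simple_polygon <- function(v) {
  n <- nrow(v)
  a <- v
  b <- v[c(2:n, 1L), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    js <- seq.int(i + 2L, jmax)
    if (segments_intersect_any(a[i, ], b[i, ], a[js, , drop = FALSE],
                               b[js, , drop = FALSE])) {
      return(FALSE)
    }
  }
  TRUE
}

# Does segment p1-p2 properly intersect (or touch) any of the segments
# q1[k,]-q2[k,]? Vectorized orientation tests.
segments_intersect_any <- function(p1, p2, q1, q2) {
  o <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  d1 <- o(p1[1], p1[2], p2[1], p2[2], q1[, 1], q1[, 2])
  d2 <- o(p1[1], p1[2], p2[1], p2[2], q2[, 1], q2[, 2])
  d3 <- o(q1[, 1], q1[, 2], q2[, 1], q2[, 2], rep(p1[1], nrow(q1)), rep(p1[2], nrow(q1)))
  d4 <- o(q1[, 1], q1[, 2], q2[, 1], q2[, 2], rep(p2[1], nrow(q1)), rep(p2[2], nrow(q1)))
  proper <- (d1 * d2 < 0) & (d3 * d4 < 0)
  if (any(proper)) return(TRUE)
  # collinear overlap / endpoint touching between non-adjacent edges
  touch <- (d1 == 0 & on_segment(p1, p2, q1)) |
           (d2 == 0 & on_segment(p1, p2, q2)) |
           (d3 == 0 & on_segment_pt(q1, q2, p1)) |
           (d4 == 0 & on_segment_pt(q1, q2, p2))
  any(touch)
}

on_segment <- function(p1, p2, q) {
  q[, 1] >= pmin(p1[1], p2[1]) & q[, 1] <= pmax(p1[1], p2[1]) &
  q[, 2] >= pmin(p1[2], p2[2]) & q[, 2] <= pmax(p1[2], p2[2])
}

on_segment_pt <- function(a, b, p) {
  p[1] >= pmin(a[, 1], b[, 1]) & p[1] <= pmax(a[, 1], b[, 1]) &
  p[2] >= pmin(a[, 2], b[, 2]) & p[2] <= pmax(a[, 2], b[, 2])
}

# Even-odd ray-casting point-in-polygon test for a matrix of points.
points_in_polygon <- function(pts, poly) {
  pts <- as.matrix(pts)
  n <- nrow(poly)
  px <- poly[, 1L]; py <- poly[, 2L]
  qx <- c(px[-1L], px[1L]); qy <- c(py[-1L], py[1L])
  vapply(seq_len(nrow(pts)), function(i) {
    x <- pts[i, 1L]; y <- pts[i, 2L]
    crosses <- ((py > y) != (qy > y)) &
      (x < (qx - px) * (y - py) / (qy - py) + px)
    sum(crosses) %% 2L == 1L
  }, logical(1))
}
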