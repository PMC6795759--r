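# Small builders used across the test files.

square_vertices <- function(side = 10, x0 = 0, y0 = 0) {
  cbind(c(x0, x0 + side, x0 + side, x0),
        c(y0, y0, y0 + side, y0 + side))
}

# Axis-aligned square contour stack: one unit-square outer contour per slice.
square_stack <- function(z, side = 10, subject_id = "sq",
                         shank_landmarks = NULL) {
  contour_stack(lapply(z, function(zi) contour(zi, square_vertices(side))),
                subject_id = subject_id, muscle_label = "SQ",
                shank_landmarks = shank_landmarks)
}

# Profile stack with prescribed per-slice areas (square cross-sections).
profile_stack <- function(z, areas, shank_landmarks = range(z)) {
  contour_stack(mapply(function(zi, a) contour(zi, square_vertices(sqrt(a))),
                       z, areas, SIMPLIFY = FALSE),
                subject_id = "prof", muscle_label = "PR",
                shank_landmarks = shank_landmarks)
}

# Random star-shaped simple polygon around the origin.
random_simple_polygon <- function(n = 50, seed = 1) {
  set.seed(seed)
  theta <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, 5, 20)
  cbind(r * cos(theta), r * sin(theta))
}

# Independent area oracle: fan triangulation from the first vertex,
# summing signed triangle areas via the cross product.
fan_triangulation_area <- function(v) {
  n <- nrow(v)
  s <- 0
  for (i in 2:(n - 1L)) {
    e1 <- v[i, ] - v[1L, ]
    e2 <- v[i + 1L, ] - v[1L, ]
    s <- s + (e1[1L] * e2[2L] - e1[2L] * e2[1L]) / 2
  }
  abs(s)
}

# Binary 3-D mask with a filled disk of radius r (voxels) on each slice.
disk_mask <- function(r_vox, n_slices, margin = 3L) {
  n <- 2L * (r_vox + margin)
  cx <- n / 2 + 0.5
  idx <- expand.grid(x = seq_len(n), y = seq_len(n))
  disk <- matrix(((idx$x - cx)^2 + (idx$y - cx)^2) <= r_vox^2, n, n) * 1L
  array(rep(disk, n_slices), dim = c(n, n, n_slices))
}
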