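# ACSA profiles, muscle length, integrated volume, peak location and the
# composed morphology measurement.

test_that("polygon_area matches hand values and the fan-triangulation oracle", {
  expect_equal(polygon_area(square_vertices(10)), 100)
  expect_equal(polygon_area(cbind(c(0, 40, 0), c(0, 0, 30))), 600)
  # orientation independence
  sq <- square_vertices(10)
  expect_equal(polygon_area(sq[rev(seq_len(4)), ]), 100)
  # repeated closing vertex tolerated
  expect_equal(polygon_area(rbind(sq, sq[1, ])), 100)
  # 50-vertex random simple polygon against two independent oracles
  v <- random_simple_polygon(50, seed = 42)
  expect_equal(polygon_area(v), fan_triangulation_area(v))
  expect_equal(polygon_area(v), abs(pracma::polyarea(v[, 1], v[, 2])))
  expect_error(polygon_area(cbind(c(0, 1, 2), c(0, 1, 2))), "degenerate")
})

test_that("acsa_profile sums outer areas and subtracts holes per slice", {
  cyl <- make_analytic_solid("cylinder", radius = 10, length = 100,
                             slice_spacing = 10)
  prof <- acsa_profile(cyl)
  expect_length(prof$z, 11L)
  expect_equal(prof$acsa, rep(100 * pi, 11L), tolerance = 1e-12)

  # two outer polygons of 50 and 30 mm^2 on one slice -> 80 mm^2
  st <- contour_stack(
    list(contour(0, square_vertices(sqrt(50))),
         contour(0, square_vertices(sqrt(30), x0 = 20)),
         contour(2, square_vertices(sqrt(50)))),
    subject_id = "s", muscle_label = "m")
  expect_equal(acsa_profile(st)$acsa, c(80, 50))

  # hole subtraction and the hole-exceeds-outer error
  st2 <- contour_stack(
    list(contour(0, square_vertices(10)),
         contour(0, square_vertices(4, 3, 3), role = "hole")),
    subject_id = "s", muscle_label = "m")
  expect_equal(acsa_profile(st2)$acsa, 84)
  st3 <- contour_stack(
    list(contour(0, square_vertices(10)),
         contour(0, square_vertices(9.99, 0.004, 0.004), role = "hole")),
    subject_id = "s", muscle_label = "m", validate = FALSE)
  st3$contours[[2]]$vertices <- square_vertices(12)  # force invalid hole
  expect_error(acsa_profile(st3), "hole area exceeds")
})

test_that("spheroid sections match the analytic ellipse-section area", {
  a <- 20; c2 <- 150  # equatorial radius, half polar axis
  sph <- make_analytic_solid("spheroid", radius = a, length = 2 * c2)
  prof <- acsa_profile(sph)
  zc <- prof$z - c2  # centred axial coordinate
  analytic <- pi * a^2 * (1 - (zc / c2)^2)
  away <- abs(zc) < 0.9 * c2  # away from the poles
  expect_true(all(abs(prof$acsa[away] - analytic[away]) /
                    analytic[away] < 0.01))
})

test_that("muscle length is the marginal-slice distance, translation-invariant", {
  z <- seq(0, 308, by = 2)
  st <- square_stack(z)
  expect_equal(muscle_length(acsa_profile(st)), 30.8)
  expect_equal(muscle_length(acsa_profile(square_stack(c(0, 5, 17)))), 1.7)
  expect_equal(muscle_length(acsa_profile(square_stack(z + 100))), 30.8)
  expect_error(muscle_length(acsa_profile(square_stack(0))), "at least 2")
})

test_that("integrate_volume matches analytic solids", {
  # constant 500 mm^2 over 100 mm -> 50 cm^3 (trapezoid exact)
  st <- profile_stack(seq(0, 100, 10), rep(500, 11))
  expect_equal(integrate_volume(acsa_profile(st)), 50)
  # cone: base 2400 mm^2, length 300 mm, 2 mm slices -> A L / 3 within 0.1%
  cone <- make_analytic_solid("cone", base_area = 2400, length = 300)
  expect_equal(integrate_volume(acsa_profile(cone)), 240, tolerance = 0.001)
  # spheroid a = b = 20, c = 125 sampled at 2 mm -> (4/3) pi a^2 c within 0.5%
  sph <- make_analytic_solid("spheroid", radius = 20, length = 250)
  expect_equal(integrate_volume(acsa_profile(sph)),
               (4 / 3) * pi * 20^2 * 125 / 1000, tolerance = 0.005)
})

test_that("find_acsa_max locates the peak and breaks ties distally", {
  z <- seq(0, 100, 10)
  inc <- profile_stack(z, seq(100, 200, 10), shank_landmarks = c(0, 100))
  pk <- find_acsa_max(acsa_profile(inc))
  expect_equal(pk$position_pct_shank, 100)  # most proximal slice
  tied <- profile_stack(z, c(1, 2, 9, 9, 2, 1, 1, 1, 1, 1, 1) * 100,
                        shank_landmarks = c(0, 100))
  expect_equal(find_acsa_max(acsa_profile(tied))$z_peak, 20)  # most distal tie
  no_lm <- profile_stack(z, seq(100, 200, 10), shank_landmarks = NULL)
  expect_error(find_acsa_max(acsa_profile(no_lm)), "landmarks")
})

test_that("measured shape factor approaches the analytic limits as spacing halves", {
  cyl <- make_analytic_solid("cylinder", radius = 10, length = 100)
  expect_equal(measure_morphology(cyl)$shape_factor, 1)
  err <- function(kind, target, h, ...) {
    abs(measure_morphology(
      make_analytic_solid(kind, slice_spacing = h, ...))$shape_factor - target)
  }
  cone_err <- vapply(c(4, 2, 1), function(h)
    err("cone", 1 / 3, h, base_area = 2400, length = 300), numeric(1))
  sph_err <- vapply(c(4, 2, 1), function(h)
    err("spheroid", 2 / 3, h, radius = 20, length = 240), numeric(1))
  expect_true(all(diff(cone_err) < 0))
  expect_true(all(diff(sph_err) < 0))
  # O(h^2): halving the spacing divides the error by about four
  expect_true(all(cone_err[-3] / cone_err[-1] > 2.5 &
                    cone_err[-3] / cone_err[-1] < 6))
})

test_that("morphology is scale-equivariant and the shape factor invariant", {
  base <- make_parametric_muscle(L_cm = 25, ACSA_max_cm2 = 13,
                                 shape_factor = 0.55, peak_relative = 0.6)
  m0 <- measure_morphology(base)
  s <- 1.7
  scaled <- base
  scaled$contours <- lapply(base$contours, function(ct) {
    contour(ct$z * s, ct$vertices * s, role = ct$role, validate = FALSE)
  })
  scaled <- contour_stack(scaled$contours, subject_id = "sc",
                          muscle_label = "m",
                          shank_landmarks = base$shank_landmarks * s,
                          validate = FALSE)
  m1 <- measure_morphology(scaled)
  expect_equal(m1$L_muscle_cm, s * m0$L_muscle_cm)
  expect_equal(m1$ACSA_max_cm2, s^2 * m0$ACSA_max_cm2)
  expect_equal(m1$V_measured_cm3, s^3 * m0$V_measured_cm3)
  expect_equal(m1$shape_factor, m0$shape_factor)

  # axial stretch only: V and L scale by k, shape factor invariant
  k <- 2.3
  stretched <- contour_stack(
    lapply(base$contours, function(ct)
      contour(ct$z * k, ct$vertices, role = ct$role, validate = FALSE)),
    subject_id = "st", muscle_label = "m",
    shank_landmarks = base$shank_landmarks * k, validate = FALSE)
  m2 <- measure_morphology(stretched)
  expect_equal(m2$L_muscle_cm, k * m0$L_muscle_cm)
  expect_equal(m2$V_measured_cm3, k * m0$V_measured_cm3)
  expect_equal(m2$shape_factor, m0$shape_factor)
})

test_that("shape factor never exceeds 1, with equality only for flat profiles", {
  set.seed(9)
  for (i in 1:10) {
    st <- make_parametric_muscle(L_cm = runif(1, 15, 35),
                                 ACSA_max_cm2 = runif(1, 5, 30),
                                 shape_factor = runif(1, 0.2, 0.9),
                                 peak_relative = runif(1, 0.2, 0.8))
    expect_lt(measure_morphology(st)$shape_factor, 1)
  }
  flat <- make_analytic_solid("cylinder", radius = 5, length = 60)
  expect_equal(measure_morphology(flat)$shape_factor, 1)
})
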