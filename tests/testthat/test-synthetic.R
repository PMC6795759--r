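# Phantom generation: profile-parameter solver, analytic solids, parametric
# muscles and cohort draws.

test_that("solve_profile_parameters matches the closed-form symmetric case", {
  # mean/max = 2/3 with central peak: integral of t(1-t) is 1/6, max 1/4
  ab <- solve_profile_parameters(2 / 3, 0.5)
  expect_equal(unname(ab), c(2, 2), tolerance = 1e-6)
  # symmetric requests always return alpha = beta
  for (p in c(0.3, 0.55, 0.8)) {
    ab <- solve_profile_parameters(p, 0.5)
    expect_equal(unname(ab["alpha"]), unname(ab["beta"]), tolerance = 1e-8)
  }
  # flattening limit: p -> 1 drives alpha, beta -> 1
  ab1 <- solve_profile_parameters(0.999, 0.4)
  expect_lt(max(abs(ab1 - 1)), 0.05)
  expect_error(solve_profile_parameters(1.2, 0.5), "between 0 and 1")
  expect_error(solve_profile_parameters(0.5, 0), "between 0 and 1")
})

test_that("solved profiles reproduce the requested mode and mean-to-max ratio", {
  grid <- expand.grid(p = c(0.35, 0.484, 0.556, 0.7), m = c(0.25, 0.6, 0.85))
  t <- seq(0, 1, length.out = 20001)
  for (i in seq_len(nrow(grid))) {
    ab <- solve_profile_parameters(grid$p[i], grid$m[i])
    g <- tsmorph:::beta_kernel(t, ab["alpha"], ab["beta"])
    expect_equal(t[which.max(g)], grid$m[i], tolerance = 1e-3)
    expect_equal(pracma::trapz(t, g) / max(g), grid$p[i], tolerance = 1e-4)
  }
})

test_that("analytic solids realize their known shape factors", {
  p <- function(st) measure_morphology(st)$shape_factor
  expect_equal(p(make_analytic_solid("cylinder", radius = 10, length = 100)), 1)
  expect_equal(p(make_analytic_solid("cone", base_area = 2400, length = 300,
                                     slice_spacing = 1)),
               1 / 3, tolerance = 0.005)
  expect_equal(p(make_analytic_solid("spheroid", radius = 20, length = 250,
                                     slice_spacing = 1)),
               2 / 3, tolerance = 0.005)
  expect_error(make_analytic_solid("cylinder", radius = -1, length = 10),
               "positive")
  expect_error(make_analytic_solid("cylinder", radius = 5, length = 10,
                                   slice_spacing = 6), "slice_spacing")
})

test_that("parametric muscles recover their generating morphology", {
  # soleus-like spec: peak placed at 59.3% shank
  st <- make_parametric_muscle(L_cm = 30.8, ACSA_max_cm2 = 24.0,
                               shape_factor = 0.484, peak_pct_shank = 59.3,
                               shank_landmarks = c(0, 380), z_offset_mm = 19)
  m <- measure_morphology(st)
  expect_equal(m$L_muscle_cm, 30.8)
  expect_equal(m$ACSA_max_cm2, 24.0)
  expect_lt(abs(m$shape_factor - 0.484), 0.01)
  # peak within one slice spacing (2 mm of 380 mm shank)
  expect_lt(abs(m$acsa_max_position_pct_shank - 59.3), 100 * 2 / 380)

  # near-flat profile: volume approaches A x L (the kernel still vanishes at
  # the muscle ends, so the approach is from below)
  flat <- make_parametric_muscle(L_cm = 20, ACSA_max_cm2 = 10,
                                 shape_factor = 0.99, peak_relative = 0.5)
  mf <- measure_morphology(flat)
  expect_equal(mf$V_measured_cm3, 0.99 * 10 * 20, tolerance = 0.015)
  expect_lt(abs(mf$shape_factor - 0.99), 0.01)

  # refining the slice grid keeps the recovery far inside tolerance at both
  # spacings (the raw sampled-max reader makes the ~1e-5 residual
  # non-monotone in h, so strict monotonicity is not asserted)
  err_at <- function(h) {
    st <- make_parametric_muscle(L_cm = 24.7, ACSA_max_cm2 = 13.1,
                                 shape_factor = 0.556, peak_relative = 0.7,
                                 slice_spacing_mm = h)
    abs(measure_morphology(st)$shape_factor - 0.556)
  }
  expect_lt(err_at(2), 1e-3)
  expect_lt(err_at(1), 1e-3)

  expect_error(make_parametric_muscle(L_cm = 20, ACSA_max_cm2 = 10,
                                      shape_factor = 0.5,
                                      peak_pct_shank = 90,
                                      shank_landmarks = c(0, 380),
                                      z_offset_mm = 0),
               "outside the muscle extent")
})

test_that("generated peak positions recover a 60%-of-shank construction", {
  st <- make_parametric_muscle(L_cm = 25, ACSA_max_cm2 = 12,
                               shape_factor = 0.55, peak_pct_shank = 60,
                               shank_landmarks = c(0, 380), z_offset_mm = 60)
  m <- measure_morphology(st)
  expect_lt(abs(m$acsa_max_position_pct_shank - 60), 100 * 2 / 380 / 2 + 1e-9)
})

test_that("cohort generation is seed-deterministic and respects degenerate SDs", {
  a <- make_cohort(n = 3, seed = 99)
  b <- make_cohort(n = 3, seed = 99)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$stacks[[5]]$contours, b$stacks[[5]]$contours)
  c2 <- make_cohort(n = 3, seed = 100)
  expect_false(identical(a$ground_truth$shape_factor,
                         c2$ground_truth$shape_factor))

  # SD = 0 everywhere: all subjects identical, CV = 0
  degen <- preset_older_female_ts()
  for (m in names(degen$muscles)) {
    for (f in c("L_cm", "ACSA_max_cm2", "shape_factor", "peak_pct_shank")) {
      degen$muscles[[m]][[f]][2] <- 0
    }
  }
  co <- make_cohort(n = 3, seed = 1, preset = degen, muscles = "GM")
  morph <- measure_cohort(co$stacks)
  expect_identical(morph$shape_factor, rep(morph$shape_factor[1], 3))
  expect_equal(coefficient_of_variation(morph$shape_factor), 0)
  expect_equal(morph$shape_factor[1], 0.556, tolerance = 0.01)

  expect_error(make_cohort(n = 3, seed = 1, muscles = "TIB"), "TIB")
  expect_error(make_cohort(n = 0, seed = 1), "at least 1")
})

test_that("generator and pipeline close: measured morphology matches ground truth", {
  co <- make_cohort(n = 6, seed = 17)
  morph <- measure_cohort(co$stacks)
  gt <- co$ground_truth
  expect_equal(morph$L_muscle_cm, gt$L_cm)
  expect_equal(morph$ACSA_max_cm2, gt$ACSA_max_cm2)
  expect_true(all(abs(morph$shape_factor - gt$shape_factor) <= 0.01))
  expect_true(all(abs(morph$acsa_max_position_pct_shank - gt$peak_pct_shank)
                  <= 100 * 2 / 380))
  # implied volume p A L matches the integrated volume within integration error
  expect_equal(morph$V_measured_cm3, gt$V_implied_cm3, tolerance = 0.01)
})

test_that("cohorts round-trip through disk and the global RNG state survives", {
  set.seed(1234); before <- .Random.seed
  co <- make_cohort(n = 2, seed = 5, muscles = c("SOL", "GM"))
  expect_identical(.Random.seed, before)  # no global random state
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  files <- list.files(dir, pattern = "\\.json$")
  expect_length(files, 4L)
  back <- read_contour_stack(file.path(dir, sprintf("%s_%s.json",
                                                    co$stacks[[1]]$subject_id,
                                                    co$stacks[[1]]$muscle_label)))
  expect_equal(measure_morphology(back), measure_morphology(co$stacks[[1]]))
  gt <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(gt), 4L)
})
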