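# Synthetic phantom generation: analytic solids with known shape factors
# and parametric cohorts whose per-subject morphology follows prescribed
# distributions, so the full contour pipeline can be validated without MRI
# data.
#
# Profile family: the ACSA along the normalized muscle axis t in [0, 1] is
# proportional to the beta kernel g(t) = t^(alpha-1) (1-t)^(beta-1) with
# alpha, beta > 1. The family is unimodal with independently controllable
# mode (peak position) and mean-to-max ratio (shape factor), the two
# quantities the pipeline must recover.

beta_kernel <- function(t, alpha, beta) {
  out <- numeric(length(t))
  inb <- t > 0 & t < 1
  out[inb] <- exp((alpha - 1) * log(t[inb]) + (beta - 1) * log(1 - t[inb]))
  out
}

# log mean-to-max ratio of the kernel along the constraint line
# alpha = 1 + s*m, beta = 1 + s*(1-m) (which pins the mode at m exactly)
log_p_of_s <- function(s, m) {
  a <- 1 + s * m
  b <- 1 + s * (1 - m)
  lbeta(a, b) - ((a - 1) * log(m) + (b - 1) * log(1 - m))
}

#' Solve beta-kernel parameters for a target shape factor and peak position
#'
#' Finds (alpha, beta) > 1 such that the continuous profile
#' ACSA(t) proportional to t^(alpha-1) (1-t)^(beta-1) has mode exactly
#' `peak_relative` and mean-to-max ratio (the continuous shape factor)
#' equal to `p_target`. The mode constraint fixes a one-parameter line
#' alpha = 1 + s*m, beta = 1 + s*(1-m) along which the ratio decreases
#' monotonically from 1 (s -> 0, flat profile) towards 0 (s -> Inf, spike),
#' so a 1-D root search suffices.
#'
#' @param p_target Target mean-to-max ratio, in (0, 1).
#' @param peak_relative Target mode within the muscle extent, in (0, 1).
#' @param tol Convergence tolerance on the ratio (default 1e-9).
#' @return Named vector `c(alpha, beta)`.
#' @export
solve_profile_parameters <- function(p_target, peak_relative, tol = 1e-9) {
  if (!is.finite(p_target) || p_target <= 0 || p_target >= 1) {
    stop("`p_target` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.finite(peak_relative) || peak_relative <= 0 || peak_relative >= 1) {
    stop("`peak_relative` must lie strictly between 0 and 1", call. = FALSE)
  }
  m <- peak_relative
  target <- log(p_target)
  f <- function(s) log_p_of_s(s, m) - target
  lo <- 1e-8
  hi <- 4
  while (f(hi) > 0) {
    hi <- hi * 2
    if (hi > 1e8) {
      stop(sprintf(
        "no beta-kernel profile with mode %.3f reaches mean/max ratio %.4f",
        m, p_target), call. = FALSE)
    }
  }
  s <- stats::uniroot(f, c(lo, hi), tol = tol)$root
  c(alpha = 1 + s * m, beta = 1 + s * (1 - m))
}

# Unit regular n-gon direction matrix scaled so that the polygon with
# vertex radius k has shoelace area exactly pi (i.e. scaling by r yields a
# polygonal section whose area equals the target circle area pi r^2).
unit_section_polygon <- function(n_vertices) {
  if (n_vertices < 8L) stop("need at least 8 vertices per contour", call. = FALSE)
  theta <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  k <- sqrt(2 * pi / (n_vertices * sin(2 * pi / n_vertices)))
  cbind(k * cos(theta), k * sin(theta))
}

# Assemble a stack of circular cross-sections with prescribed areas (mm^2)
# at axial positions z (mm). Areas are realized exactly by area-corrected
# regular polygons, so in-plane discretization contributes no area error.
circular_section_stack <- function(z, areas_mm2, n_vertices, subject_id,
                                   muscle_label, shank_landmarks) {
  U <- unit_section_polygon(n_vertices)
  radii <- sqrt(areas_mm2 / pi)
  contours <- lapply(seq_along(z), function(i) {
    contour(z[i], radii[i] * U, role = "outer", validate = FALSE)
  })
  contour_stack(contours, subject_id = subject_id,
                muscle_label = muscle_label,
                shank_landmarks = shank_landmarks, validate = FALSE)
}

# Axial slice grid covering [0, L] at spacing h, always including both
# marginal positions so the measured length equals L exactly.
slice_grid <- function(L, h) {
  z <- seq(0, L, by = h)
  if (max(z) < L) z <- c(z, L)
  z
}

# Smallest section area kept on marginal slices where the analytic section
# vanishes; a zero-area contour is not a polygon. 0.01 mm^2 contributes
# < 0.1 mm^3 to any realistic muscle volume.
MIN_SECTION_AREA_MM2 <- 0.01

#' Generate an analytic solid as a contour stack
#'
#' Builds slice-wise polygonal sections of a solid of revolution with a
#' known shape factor: cylinder (p = 1), cone (p = 1/3) or prolate spheroid
#' (p = 2/3). Section polygons are regular n-gons radius-corrected so that
#' each polygon area equals the analytic section area exactly; the only
#' discretization left is axial, which is what the integration tests probe.
#'
#' @param kind `"cylinder"`, `"cone"` or `"spheroid"`.
#' @param radius Maximal section radius, mm (cone base radius, spheroid
#'   equatorial radius). Alternatively give `base_area` (mm^2).
#' @param length Axial extent, mm (for the spheroid: the full polar axis).
#' @param slice_spacing Axial slice spacing, mm (default 2, must be
#'   < length/2).
#' @param vertices_per_contour Polygon resolution (default 32, minimum 8).
#' @param base_area Optional maximal section area in mm^2, overriding
#'   `radius`.
#' @param subject_id,muscle_label Metadata for the resulting stack.
#' @return A [contour_stack()] with shank landmarks spanning the solid.
#' @export
make_analytic_solid <- function(kind = c("cylinder", "cone", "spheroid"),
                                radius = NULL, length = NULL,
                                slice_spacing = 2,
                                vertices_per_contour = 32L,
                                base_area = NULL,
                                subject_id = "phantom",
                                muscle_label = kind) {
  kind <- match.arg(kind)
  muscle_label <- muscle_label[1L]
  if (!is.null(base_area)) {
    if (base_area <= 0) stop("`base_area` must be positive", call. = FALSE)
    radius <- sqrt(base_area / pi)
  }
  if (is.null(radius) || radius <= 0 || is.null(length) || length <= 0) {
    stop("positive `radius` (or `base_area`) and `length` are required",
         call. = FALSE)
  }
  if (slice_spacing <= 0 || slice_spacing >= length / 2) {
    stop("`slice_spacing` must be positive and smaller than length/2",
         call. = FALSE)
  }
  z <- slice_grid(length, slice_spacing)
  u <- z / length
  areas <- switch(kind,
    cylinder = rep(pi * radius^2, length(z)),
    cone     = pi * (radius * (1 - u))^2,       # apex proximal
    spheroid = pi * radius^2 * (1 - (2 * u - 1)^2))
  areas <- pmax(areas, MIN_SECTION_AREA_MM2)
  circular_section_stack(z, areas, vertices_per_contour, subject_id,
                         muscle_label, shank_landmarks = c(0, length))
}

#' Generate a parametric muscle phantom
#'
#' Builds a contour stack of circular cross-sections whose areas follow a
#' beta-kernel profile solved from the requested shape factor and peak
#' position ([solve_profile_parameters()]). The sampled maximum equals
#' `ACSA_max_cm2` exactly and the axial extent equals `L_cm` exactly, so the
#' pipeline-measured morphology recovers the specification up to axial
#' discretization (shape factor within 0.01, peak within one slice spacing
#' at the default 2 mm).
#'
#' @param L_cm Muscle length, cm.
#' @param ACSA_max_cm2 Maximal ACSA, cm^2.
#' @param shape_factor Target mean-to-max ratio p, in (0, 1).
#' @param peak_relative Profile mode within the muscle extent, in (0, 1).
#'   Alternatively give `peak_pct_shank` (with shank landmarks), from which
#'   the mode is derived.
#' @param shank_landmarks `c(z_distal, z_proximal)` mm; defaults to the
#'   muscle extent itself when neither landmarks nor `peak_pct_shank` are
#'   given.
#' @param z_offset_mm Axial position of the muscle's distal end within the
#'   shank frame (default 0).
#' @param peak_pct_shank Optional target peak position in percent of shank
#'   length.
#' @param slice_spacing_mm Slice spacing (default 2 mm, the segmentation
#'   interval the pipeline is designed around).
#' @param vertices_per_contour Polygon resolution (default 32).
#' @param subject_id,muscle_label Metadata.
#' @return A [contour_stack()]; attribute `"ground_truth"` carries the
#'   generating parameters including the implied volume p x A x L.
#' @export
make_parametric_muscle <- function(L_cm, ACSA_max_cm2, shape_factor,
                                   peak_relative = NULL,
                                   shank_landmarks = NULL,
                                   z_offset_mm = 0,
                                   peak_pct_shank = NULL,
                                   slice_spacing_mm = 2,
                                   vertices_per_contour = 32L,
                                   subject_id = "synthetic",
                                   muscle_label = "muscle") {
  if (L_cm <= 0 || ACSA_max_cm2 <= 0) {
    stop("`L_cm` and `ACSA_max_cm2` must be positive", call. = FALSE)
  }
  L_mm <- 10 * L_cm
  if (slice_spacing_mm <= 0 || slice_spacing_mm >= L_mm / 2) {
    stop("`slice_spacing_mm` must be positive and smaller than the muscle",
         call. = FALSE)
  }
  if (is.null(shank_landmarks)) {
    shank_landmarks <- c(z_offset_mm, z_offset_mm + L_mm)
  }
  if (is.null(peak_relative)) {
    if (is.null(peak_pct_shank)) {
      stop("give either `peak_relative` or `peak_pct_shank`", call. = FALSE)
    }
    S <- shank_landmarks[2L] - shank_landmarks[1L]
    z_peak <- shank_landmarks[1L] + peak_pct_shank / 100 * S
    peak_relative <- (z_peak - z_offset_mm) / L_mm
    if (peak_relative <= 0 || peak_relative >= 1) {
      stop(sprintf(
        "peak at %.1f%% shank falls outside the muscle extent [%g, %g] mm",
        peak_pct_shank, z_offset_mm, z_offset_mm + L_mm), call. = FALSE)
    }
  }
  ab <- solve_profile_parameters(shape_factor, peak_relative)
  z_local <- slice_grid(L_mm, slice_spacing_mm)
  g <- beta_kernel(z_local / L_mm, ab["alpha"], ab["beta"])
  areas <- pmax(100 * ACSA_max_cm2 * g / max(g), MIN_SECTION_AREA_MM2)
  stack <- circular_section_stack(z_local + z_offset_mm, areas,
                                  vertices_per_contour, subject_id,
                                  muscle_label, shank_landmarks)
  S <- shank_landmarks[2L] - shank_landmarks[1L]
  attr(stack, "ground_truth") <- data.frame(
    subject_id = subject_id, muscle_label = muscle_label,
    L_cm = L_cm, ACSA_max_cm2 = ACSA_max_cm2,
    shape_factor = shape_factor,
    peak_relative = peak_relative,
    peak_pct_shank = 100 * (z_offset_mm + peak_relative * L_mm -
                              shank_landmarks[1L]) / S,
    V_implied_cm3 = shape_factor * ACSA_max_cm2 * L_cm,
    alpha = unname(ab["alpha"]), beta = unname(ab["beta"]),
    stringsAsFactors = FALSE)
  stack
}

#' Built-in cohort preset: older female triceps surae
#'
#' Per-muscle means and SDs of muscle length, maximal ACSA, shape factor
#' and peak position (percent of shank length) describing a cohort of
#' healthy older female adults (n = 21, 60-75 years). The soleus attaches
#' distally (distal end at 5% shank); both gastrocnemii attach proximally
#' (proximal end at the tibial plateau). Shank length defaults to 380 mm,
#' a representative calcaneal-tuberosity-to-tibial-plateau distance for
#' women of about 165 cm stature.
#'
#' @return A list usable as the `preset` argument of [make_cohort()]:
#'   `name`, `shank_length_mm`, and per-muscle parameter list with entries
#'   `L_cm`, `ACSA_max_cm2`, `shape_factor`, `peak_pct_shank` (each
#'   `c(mean, sd)`) plus `attach` (`"distal"` or `"proximal"`).
#' @export
preset_older_female_ts <- function() {
  list(
    name = "OLDER-FEMALE-TS",
    shank_length_mm = 380,
    muscles = list(
      SOL = list(L_cm = c(30.8, 0.7), ACSA_max_cm2 = c(24.0, 4.4),
                 shape_factor = c(0.484, 0.027),
                 peak_pct_shank = c(59.3, 3.5), attach = "distal"),
      GM  = list(L_cm = c(24.7, 1.4), ACSA_max_cm2 = c(13.1, 2.3),
                 shape_factor = c(0.556, 0.028),
                 peak_pct_shank = c(75.0, 4.3), attach = "proximal"),
      GL  = list(L_cm = c(21.2, 2.1), ACSA_max_cm2 = c(7.6, 1.2),
                 shape_factor = c(0.568, 0.049),
                 peak_pct_shank = c(80.6, 5.1), attach = "proximal")))
}

# One truncated-normal draw: normal(mean, sd) restricted to
# [mean - 3 sd, mean + 3 sd] intersected with (lower, upper), by rejection.
rtrunc_one <- function(mean, sd, lower = -Inf, upper = Inf,
                       max_tries = 1000L) {
  if (sd == 0) {
    if (mean <= lower || mean >= upper) {
      stop("degenerate draw outside feasible bounds", call. = FALSE)
    }
    return(mean)
  }
  lo <- max(lower, mean - 3 * sd)
  hi <- min(upper, mean + 3 * sd)
  if (lo >= hi) stop("empty feasible range for truncated draw", call. = FALSE)
  for (i in seq_len(max_tries)) {
    x <- stats::rnorm(1L, mean, sd)
    if (x > lo && x < hi) return(x)
  }
  stop("no feasible draw after bounded retries", call. = FALSE)
}

#' Generate a synthetic cohort of muscle phantoms
#'
#' Draws per-subject muscle parameters (length, maximal ACSA, shape factor,
#' peak position) independently from truncated normal distributions
#' (truncation at +/- 3 SD and at feasibility bounds) and builds one
#' contour stack per (subject, muscle) with [make_parametric_muscle()].
#' All randomness flows from the explicit `seed`; the caller's random
#' state is left untouched.
#'
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed (required).
#' @param preset Cohort parameter set; default [preset_older_female_ts()].
#' @param muscles Subset of muscle labels to generate (default: all in the
#'   preset).
#' @param slice_spacing_mm Slice spacing (default 2 mm).
#' @param vertices_per_contour Polygon resolution (default 32).
#' @return List with `stacks` (list of [contour_stack()], one per subject x
#'   muscle) and `ground_truth` (data frame of generating parameters with
#'   the implied volume p x A x L per muscle).
#' @export
make_cohort <- function(n, seed, preset = preset_older_female_ts(),
                        muscles = names(preset$muscles),
                        slice_spacing_mm = 2, vertices_per_contour = 32L) {
  if (n < 1L) stop("`n` must be at least 1", call. = FALSE)
  if (missing(seed) || is.null(seed)) {
    stop("an explicit `seed` is required", call. = FALSE)
  }
  missing_m <- setdiff(muscles, names(preset$muscles))
  if (length(missing_m)) {
    stop(sprintf("preset '%s' has no parameters for muscle(s): %s",
                 preset$name, paste(missing_m, collapse = ", ")),
         call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  S <- preset$shank_length_mm
  stacks <- vector("list", n * length(muscles))
  truth <- vector("list", n * length(muscles))
  k <- 0L
  for (i in seq_len(n)) {
    sid <- sprintf("S%03d", i)
    for (m in muscles) {
      pm <- preset$muscles[[m]]
      draw <- NULL
      for (try in 1:100) {
        L_cm <- rtrunc_one(pm$L_cm[1L], pm$L_cm[2L], lower = 2)
        A <- rtrunc_one(pm$ACSA_max_cm2[1L], pm$ACSA_max_cm2[2L], lower = 0.5)
        p <- rtrunc_one(pm$shape_factor[1L], pm$shape_factor[2L],
                        lower = 0.05, upper = 0.995)
        peak <- rtrunc_one(pm$peak_pct_shank[1L], pm$peak_pct_shank[2L],
                           lower = 1, upper = 99)
        L_mm <- 10 * L_cm
        z0 <- if (identical(pm$attach, "proximal")) S - L_mm else 0.05 * S
        mode <- (peak / 100 * S - z0) / L_mm
        if (z0 >= 0 && z0 + L_mm <= S && mode > 0.02 && mode < 0.98) {
          draw <- list(L_cm = L_cm, A = A, p = p, peak = peak, z0 = z0)
          break
        }
      }
      if (is.null(draw)) {
        stop(sprintf("no feasible parameters for muscle %s after 100 retries", m),
             call. = FALSE)
      }
      stack <- make_parametric_muscle(
        L_cm = draw$L_cm, ACSA_max_cm2 = draw$A, shape_factor = draw$p,
        peak_pct_shank = draw$peak, shank_landmarks = c(0, S),
        z_offset_mm = draw$z0, slice_spacing_mm = slice_spacing_mm,
        vertices_per_contour = vertices_per_contour,
        subject_id = sid, muscle_label = m)
      k <- k + 1L
      stacks[[k]] <- stack
      truth[[k]] <- attr(stack, "ground_truth")
    }
  }
  list(stacks = stacks,
       ground_truth = do.call(rbind, truth),
       preset_name = preset$name, seed = as.integer(seed))
}

#' Write a synthetic cohort to disk
#'
#' One contour JSON file per (subject, muscle) plus `ground_truth.csv` with
#' the generating parameters.
#'
#' @param cohort A [make_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory path.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (stack in cohort$stacks) {
    fn <- file.path(dir, sprintf("%s_%s.json", stack$subject_id,
                                 stack$muscle_label))
    write_contour_stack(stack, fn, format = "json")
  }
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
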