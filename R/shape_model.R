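# The shape-factor model: factor extraction from measured morphology,
# simplified volume estimation, and cohort factor tables.

#' Muscle shape factor
#'
#' The dimensionless ratio p = V_measured / (ACSA_max x L_muscle):
#' equivalently the mean-to-max ratio of the ACSA profile. A cylinder has
#' p = 1, a cone 1/3, a spheroid 2/3.
#'
#' @param V_measured Measured muscle volume, cm^3.
#' @param ACSA_max Maximal anatomical cross-sectional area, cm^2.
#' @param L_muscle Muscle length, cm.
#' @return Shape factor p (dimensionless).
#' @export
shape_factor <- function(V_measured, ACSA_max, L_muscle) {
  if (any(V_measured <= 0) || any(ACSA_max <= 0) || any(L_muscle <= 0)) {
    stop("V_measured, ACSA_max and L_muscle must all be positive", call. = FALSE)
  }
  V_measured / (ACSA_max * L_muscle)
}

#' Simplified muscle volume estimate
#'
#' V_estimated = p x ACSA_max x L_muscle: the simplified assessment that
#' replaces whole-muscle segmentation by a single maximal cross-section, the
#' muscle length and a muscle-specific shape factor.
#'
#' @param p Shape factor (dimensionless, in (0, 1]).
#' @param ACSA_max Maximal ACSA, cm^2.
#' @param L_muscle Muscle length, cm.
#' @return Estimated volume, cm^3.
#' @export
estimate_volume <- function(p, ACSA_max, L_muscle) {
  if (any(p <= 0) || any(ACSA_max <= 0) || any(L_muscle <= 0)) {
    stop("p, ACSA_max and L_muscle must all be positive", call. = FALSE)
  }
  p * ACSA_max * L_muscle
}

#' Construct a shape-factor table
#'
#' @param factors Named numeric vector: muscle label -> mean shape factor.
#' @param cohort_label Cohort name.
#' @param dispersion Optional named numeric vector of SDs, same names.
#' @param n Optional number of subjects the factors were averaged over.
#' @return An object of class `shape_factor_table`.
#' @export
factor_table <- function(factors, cohort_label, dispersion = NULL, n = NULL) {
  factors <- unlist(factors)
  if (is.null(names(factors)) || any(!nzchar(names(factors)))) {
    stop("`factors` must be a named vector (muscle label -> p)", call. = FALSE)
  }
  if (any(factors <= 0 | factors > 1)) {
    stop("shape factors must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(dispersion)) {
    dispersion <- unlist(dispersion)
    if (!all(names(factors) %in% names(dispersion))) {
      stop("`dispersion` must cover every muscle in `factors`", call. = FALSE)
    }
    dispersion <- dispersion[names(factors)]
  }
  structure(list(cohort_label = as.character(cohort_label),
                 factors = factors, dispersion = dispersion, n = n),
            class = "shape_factor_table")
}

#' @export
print.shape_factor_table <- function(x, ...) {
  cat(sprintf("<shape_factor_table> cohort %s\n", x$cohort_label))
  for (m in names(x$factors)) {
    if (!is.null(x$dispersion)) {
      cat(sprintf("  %-4s p = %.3f +/- %.3f\n", m, x$factors[[m]],
                  x$dispersion[[m]]))
    } else {
      cat(sprintf("  %-4s p = %.3f\n", m, x$factors[[m]]))
    }
  }
  invisible(x)
}

#' Built-in shape-factor table: older female adults
#'
#' Mean (+/- SD) triceps-surae shape factors of a cohort of 21 healthy older
#' female adults (60-75 years).
#'
#' @return A [factor_table()] with factors SOL 0.484, GM 0.556, GL 0.568.
#' @export
older_factor_table <- function() {
  factor_table(c(SOL = 0.484, GM = 0.556, GL = 0.568),
               cohort_label = "OLDER",
               dispersion = c(SOL = 0.027, GM = 0.028, GL = 0.049),
               n = 21L)
}

#' Built-in shape-factor table: young adults
#'
#' Mean triceps-surae shape factors reported for a reference group of 13
#' healthy young adults, used here for cross-age validation of the
#' simplified volume assessment.
#'
#' @return A [factor_table()] with factors SOL 0.496, GM 0.592, GL 0.569.
#' @export
young_factor_table <- function() {
  factor_table(c(SOL = 0.496, GM = 0.592, GL = 0.569),
               cohort_label = "YOUNG", n = 13L)
}

#' Average per-subject shape factors into a cohort table
#'
#' Per-muscle unweighted arithmetic mean and sample SD of the individual
#' shape factors.
#'
#' @param morphologies Data frame of per-muscle morphology rows as returned
#'   by [measure_morphology()] / [measure_cohort()].
#' @param cohort_label Name for the resulting table.
#' @return A [factor_table()].
#' @export
build_factor_table <- function(morphologies, cohort_label) {
  req <- c("muscle_label", "shape_factor")
  if (!all(req %in% names(morphologies))) {
    stop("`morphologies` must have columns muscle_label and shape_factor",
         call. = FALSE)
  }
  counts <- table(morphologies$muscle_label)
  few <- names(counts)[counts < 2L]
  if (length(few)) {
    stop(sprintf("need at least 2 subjects per muscle; too few for: %s",
                 paste(few, collapse = ", ")), call. = FALSE)
  }
  means <- tapply(morphologies$shape_factor, morphologies$muscle_label, mean)
  sds <- tapply(morphologies$shape_factor, morphologies$muscle_label,
                stats::sd)
  factor_table(stats::setNames(as.vector(means), names(means)), cohort_label,
               dispersion = stats::setNames(as.vector(sds), names(sds)),
               n = as.integer(min(counts)))
}

#' Estimate volumes for a cohort from a shape-factor table
#'
#' Applies the simplified estimator to every (subject, muscle) row using the
#' table's mean factor for that muscle and the subject's own measured
#' ACSA_max and muscle length.
#'
#' @param morphologies Data frame of morphology rows (needs `subject_id`,
#'   `muscle_label`, `ACSA_max_cm2`, `L_muscle_cm`).
#' @param table A [factor_table()] covering every muscle in `morphologies`.
#' @return Data frame with columns `subject_id`, `muscle_label`,
#'   `V_estimated_cm3`, `factor_source`.
#' @export
cross_estimate <- function(morphologies, table) {
  stopifnot(inherits(table, "shape_factor_table"))
  missing <- setdiff(unique(morphologies$muscle_label), names(table$factors))
  if (length(missing)) {
    stop(sprintf("no shape factor in table '%s' for muscle(s): %s",
                 table$cohort_label, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  p <- table$factors[morphologies$muscle_label]
  data.frame(subject_id = morphologies$subject_id,
             muscle_label = morphologies$muscle_label,
             V_estimated_cm3 = estimate_volume(unname(p),
                                               morphologies$ACSA_max_cm2,
                                               morphologies$L_muscle_cm),
             factor_source = table$cohort_label,
             stringsAsFactors = FALSE)
}

#' Read a shape-factor table from JSON
#'
#' Schema: `{cohort_label, factors: {SOL: p, ...}, dispersion: {...}}` with
#' `dispersion` optional.
#'
#' @param path JSON file path.
#' @return A [factor_table()].
#' @export
read_factor_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$cohort_label) || is.null(x$factors)) {
    stop(sprintf("factor table '%s' must define cohort_label and factors", path),
         call. = FALSE)
  }
  factor_table(unlist(x$factors), x$cohort_label,
               dispersion = if (!is.null(x$dispersion)) unlist(x$dispersion),
               n = x$n)
}

#' Write a shape-factor table to JSON
#'
#' @param table A [factor_table()].
#' @param path Output file path.
#' @export
write_factor_table <- function(table, path) {
  stopifnot(inherits(table, "shape_factor_table"))
  out <- list(cohort_label = table$cohort_label,
              factors = as.list(table$factors))
  if (!is.null(table$dispersion)) out$dispersion <- as.list(table$dispersion)
  if (!is.null(table$n)) out$n <- table$n
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
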