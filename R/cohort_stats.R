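# Agreement and group-comparison statistics for the volume-estimation
# validation: relative RMS difference, coefficient of determination,
# coefficient of variation, paired t test with normality check, one-way
# ANOVA with Bonferroni post hoc, and the full cohort validation report.

#' Relative RMS difference between estimated and measured volumes
#'
#' Default (`method = "per_subject"`): the root mean square of per-subject
#' relative differences, 100 * sqrt(mean(((est - meas)/meas)^2)). The
#' alternative normalization (`method = "pooled"`) divides the RMS of
#' absolute differences by the cohort mean measured volume.
#'
#' @param v_estimated,v_measured Equal-length numeric vectors, cm^3; all
#'   measured values positive.
#' @param method Normalization convention; see Details.
#' @return Relative RMS difference in percent.
#' @export
relative_rms <- function(v_estimated, v_measured,
                         method = c("per_subject", "pooled")) {
  method <- match.arg(method)
  if (length(v_estimated) != length(v_measured)) {
    stop("estimated and measured vectors must have equal length", call. = FALSE)
  }
  if (!length(v_measured) || any(v_measured <= 0)) {
    stop("need at least one pair and all measured volumes positive",
         call. = FALSE)
  }
  if (method == "per_subject") {
    100 * sqrt(mean(((v_estimated - v_measured) / v_measured)^2))
  } else {
    100 * sqrt(mean((v_estimated - v_measured)^2)) / mean(v_measured)
  }
}

#' Coefficient of determination between estimated and measured volumes
#'
#' Squared Pearson correlation. This definition is invariant under positive
#' rescaling of either vector, which is why swapping one cohort's mean shape
#' factor for another's leaves R^2 unchanged (the per-subject ACSA_max and
#' length are identical in both estimates).
#'
#' @param v_estimated,v_measured Numeric vectors, >= 3 pairs, each with
#'   nonzero variance.
#' @return R^2 in `[0, 1]`.
#' @export
r_squared <- function(v_estimated, v_measured) {
  if (length(v_estimated) != length(v_measured)) {
    stop("estimated and measured vectors must have equal length", call. = FALSE)
  }
  if (length(v_measured) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(v_estimated) == 0 || stats::sd(v_measured) == 0) {
    stop("zero variance: R^2 undefined", call. = FALSE)
  }
  stats::cor(v_estimated, v_measured)^2
}

#' Coefficient of variation
#'
#' 100 * sample SD / mean; used for the inter-subject variability of shape
#' factors and ACSA_max positions.
#'
#' @param values Numeric vector with >= 2 values and nonzero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("zero mean: CV undefined", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Paired comparison of estimated and measured volumes
#'
#' Two-sided paired t test on the differences, preceded by a
#' Kolmogorov-Smirnov normality check on the differences. Because the
#' normal's parameters are estimated from the sample, the Lilliefors
#' correction is applied ([nortest::lillie.test()]).
#'
#' @param v_estimated,v_measured Numeric vectors, >= 3 pairs.
#' @param alpha Significance level (default 0.05).
#' @return List with `normality_p` (NA when n < 5, below the Lilliefors
#'   minimum), `mean_difference`, `t_statistic`, `df`, `p_value`,
#'   `significant`, `degenerate` (TRUE when the differences are constant and
#'   no test is possible).
#' @export
paired_comparison <- function(v_estimated, v_measured, alpha = 0.05) {
  if (length(v_estimated) != length(v_measured)) {
    stop("estimated and measured vectors must have equal length", call. = FALSE)
  }
  n <- length(v_measured)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)
  d <- v_estimated - v_measured
  if (stats::sd(d) == 0) {
    return(list(normality_p = NA_real_, mean_difference = mean(d),
                t_statistic = NA_real_, df = n - 1L, p_value = NA_real_,
                significant = FALSE, degenerate = TRUE))
  }
  normality_p <- if (n >= 5L) nortest::lillie.test(d)$p.value else NA_real_
  tt <- stats::t.test(v_estimated, v_measured, paired = TRUE)
  list(normality_p = normality_p,
       mean_difference = unname(tt$estimate),
       t_statistic = unname(tt$statistic),
       df = unname(tt$parameter),
       p_value = tt$p.value,
       significant = tt$p.value < alpha,
       degenerate = FALSE)
}

#' One-way ANOVA across muscles with Bonferroni post hoc
#'
#' Fixed-effects one-way ANOVA with muscle as factor, followed by pairwise
#' pooled-SD t tests with Bonferroni adjustment. Muscles measured in the
#' same subjects are strictly repeated measures; the independent-groups
#' ANOVA is used deliberately (it is the conventional analysis in this
#' literature) and the report carries a note to that effect.
#'
#' @param values_by_muscle Named list: muscle label -> numeric vector of
#'   per-subject values; >= 2 groups with >= 2 values each.
#' @param alpha Significance level (default 0.05).
#' @return List with `F_statistic`, `df`, `p_value`, `pairwise` (data frame
#'   of Bonferroni-adjusted pairwise comparisons with `significant` flags)
#'   and `note`.
#' @export
muscle_anova <- function(values_by_muscle, alpha = 0.05) {
  if (length(values_by_muscle) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- lengths(values_by_muscle)
  if (any(sizes < 2L)) {
    stop(sprintf("group(s) with fewer than 2 values: %s",
                 paste(names(values_by_muscle)[sizes < 2L], collapse = ", ")),
         call. = FALSE)
  }
  values <- unlist(values_by_muscle, use.names = FALSE)
  muscle <- factor(rep(names(values_by_muscle), sizes),
                   levels = names(values_by_muscle))
  fit <- stats::aov(values ~ muscle)
  s <- summary(fit)[[1L]]
  pw <- stats::pairwise.t.test(values, muscle, p.adjust.method = "bonferroni",
                               pool.sd = TRUE)
  pm <- pw$p.value
  pairs <- which(!is.na(pm), arr.ind = TRUE)
  pairwise <- data.frame(
    muscle_a = rownames(pm)[pairs[, 1L]],
    muscle_b = colnames(pm)[pairs[, 2L]],
    p_adjusted = pm[pairs],
    stringsAsFactors = FALSE)
  pairwise$significant <- pairwise$p_adjusted < alpha
  list(F_statistic = s[["F value"]][1L],
       df = c(s[["Df"]][1L], s[["Df"]][2L]),
       p_value = s[["Pr(>F)"]][1L],
       pairwise = pairwise,
       note = paste("one-way ANOVA treats muscles as independent groups;",
                    "muscles are repeated measures within subject"))
}

#' Full cohort validation of the shape-factor volume assessment
#'
#' For each supplied shape-factor table, estimates every muscle volume from
#' the cohort's measured ACSA_max and muscle length, then computes per
#' muscle the agreement statistics between estimated and measured volume
#' (relative RMS, R^2, paired t test with normality check). Also reports the
#' inter-subject CV of shape factors and peak positions per muscle and the
#' across-muscle ANOVA of the shape factor.
#'
#' @param morphologies Data frame of measured morphology rows
#'   ([measure_cohort()] output) covering every muscle in every table.
#' @param tables A [factor_table()] or list of them.
#' @param alpha Significance level (default 0.05).
#' @param rms_method Normalization for [relative_rms()].
#' @return An object of class `cohort_validation`: list with `agreement`
#'   (data frame, one row per muscle x table), `variability` (per-muscle CVs),
#'   `anova` (shape-factor ANOVA), `meta`.
#' @export
validate_cohort <- function(morphologies, tables, alpha = 0.05,
                            rms_method = c("per_subject", "pooled")) {
  rms_method <- match.arg(rms_method)
  if (inherits(tables, "shape_factor_table")) tables <- list(tables)
  muscles <- unique(morphologies$muscle_label)
  agreement <- do.call(rbind, lapply(tables, function(tab) {
    est <- cross_estimate(morphologies, tab)
    do.call(rbind, lapply(muscles, function(m) {
      sel <- morphologies$muscle_label == m
      vm <- morphologies$V_measured_cm3[sel]
      ve <- est$V_estimated_cm3[est$muscle_label == m]
      pc <- paired_comparison(ve, vm, alpha = alpha)
      data.frame(factor_table = tab$cohort_label, muscle_label = m,
                 n = sum(sel),
                 rms_relative_pct = relative_rms(ve, vm, method = rms_method),
                 r_squared = r_squared(ve, vm),
                 mean_difference_cm3 = pc$mean_difference,
                 normality_p = pc$normality_p,
                 t_statistic = pc$t_statistic,
                 p_value = pc$p_value,
                 significant = pc$significant,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(agreement) <- NULL
  variability <- do.call(rbind, lapply(muscles, function(m) {
    sel <- morphologies$muscle_label == m
    data.frame(muscle_label = m,
               shape_factor_cv_pct =
                 coefficient_of_variation(morphologies$shape_factor[sel]),
               peak_position_cv_pct =
                 coefficient_of_variation(
                   morphologies$acsa_max_position_pct_shank[sel]),
               stringsAsFactors = FALSE)
  }))
  anova <- if (length(muscles) >= 2L &&
               all(table(morphologies$muscle_label) >= 2L)) {
    muscle_anova(split(morphologies$shape_factor, morphologies$muscle_label),
                 alpha = alpha)
  }
  structure(list(agreement = agreement, variability = variability,
                 anova = anova,
                 meta = list(n_subjects = length(unique(morphologies$subject_id)),
                             alpha = alpha, rms_method = rms_method,
                             factor_tables = vapply(tables, function(t)
                               t$cohort_label, character(1)))),
            class = "cohort_validation")
}

#' @export
print.cohort_validation <- function(x, digits = 3, ...) {
  cat(sprintf("<cohort_validation> %d subjects, alpha = %g, RMS method = %s\n",
              x$meta$n_subjects, x$meta$alpha, x$meta$rms_method))
  cat("\nAgreement (estimated vs measured volume):\n")
  print(format(x$agreement, digits = digits), row.names = FALSE)
  cat("\nInter-subject variability:\n")
  print(format(x$variability, digits = digits), row.names = FALSE)
  if (!is.null(x$anova)) {
    cat(sprintf("\nShape-factor ANOVA: F(%d, %d) = %.2f, p = %.3g\n",
                x$anova$df[1L], x$anova$df[2L], x$anova$F_statistic,
                x$anova$p_value))
    print(format(x$anova$pairwise, digits = digits), row.names = FALSE)
    cat("note:", x$anova$note, "\n")
  }
  invisible(x)
}

#' Serialize a cohort validation report to JSON
#'
#' @param report A `cohort_validation` object.
#' @param path Output JSON path.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "cohort_validation"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
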