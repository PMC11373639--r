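#' Narrow-sense heritability per time point
#'
#' `h2_i = sigma2_g(i) / (sigma2_g(i) + sigma2_e(i))`: the additive genetic
#' variance at storage time point `i` over the total variance at that time
#' point, taken from the fitted genetic and residual covariance matrices.
#'
#' @param components A `covariance_components` object (the `components`
#'   element of a [fit_longitudinal()] result), or a list with matrices
#'   `sigma_t` and `sigma_e`.
#' @return Data frame with columns `time_point` and `h2`.
#' @export
heritability <- function(components) {
  st <- components$sigma_t
  se <- components$sigma_e
  vg <- diag(as.matrix(st))
  ve <- diag(as.matrix(se))
  if (any(vg < 0) || any(ve < 0)) stopf("negative variance component")
  tot <- vg + ve
  if (any(tot == 0)) {
    stopf("total variance is zero at time point(s): %s",
          paste(colnames(st)[tot == 0] %||% which(tot == 0), collapse = ", "))
  }
  data.frame(time_point = colnames(st) %||% paste0("t", seq_along(vg)),
             h2 = vg / tot, row.names = NULL, stringsAsFactors = FALSE)
}

#' Genetic correlations between time points
#'
#' Rescales the genetic covariance matrix to unit diagonal. Time points with
#' zero genetic variance get `NA` correlations (undefined).
#'
#' @param components As in [heritability()].
#' @return Correlation matrix with `NA` rows/columns where the genetic
#'   variance is zero.
#' @export
genetic_correlations <- function(components) {
  st <- as.matrix(components$sigma_t)
  v <- diag(st)
  s <- sqrt(pmax(v, 0))
  out <- st / tcrossprod(s)
  out[v <= 0, ] <- NA_real_
  out[, v <= 0] <- NA_real_
  diag(out)[v > 0] <- 1
  out
}

# Rep-average and (optionally) remove per-(trait, time, year) means, then
# return one value per genotype for the requested trait/time (checks are
# averaged over years).
genotype_values <- function(table, trait, time, adjust = c("year", "none")) {
  adjust <- match.arg(adjust)
  df <- as.data.frame(average_reps(table))
  df <- df[df$trait == trait & as.character(df$time_point) == time &
             !is.na(df$value), , drop = FALSE]
  if (nrow(df) == 0) return(stats::setNames(numeric(0), character(0)))
  if (adjust == "year") {
    df$value <- df$value - stats::ave(df$value, df$year)
  }
  agg <- tapply(df$value, df$genotype_id, mean)
  stats::setNames(as.numeric(agg), names(agg))
}

#' Phenotypic correlation between two trait/time combinations
#'
#' Pearson correlation across genotypes between the values of trait `a` at
#' time `a` and trait `b` at time `b`. Because genotypes were phenotyped in
#' different years, values are rep-averaged and year-adjusted (year means
#' removed within trait/time) by default; `adjust = "none"` uses raw
#' rep-averaged values.
#'
#' @param table A [phenotype_table()].
#' @param trait_a,trait_b Trait names.
#' @param time_a,time_b Time point labels.
#' @param adjust `"year"` (default) or `"none"`.
#' @return Pearson correlation coefficient.
#' @export
phenotypic_correlation <- function(table, trait_a, trait_b, time_a, time_b,
                                   adjust = c("year", "none")) {
  adjust <- match.arg(adjust)
  va <- genotype_values(table, trait_a, time_a, adjust)
  vb <- genotype_values(table, trait_b, time_b, adjust)
  common <- intersect(names(va), names(vb))
  if (length(common) < 3) {
    stopf("need >= 3 genotypes with both values (found %d)", length(common))
  }
  stats::cor(va[common], vb[common])
}

#' Variance explained by a baseline time point
#'
#' Ordinary least squares of a trait at a later storage time on the same
#' trait at a baseline time, across genotypes; returns the coefficient of
#' determination R-squared. Quantifies how well performance at harvest
#' predicts performance after storage.
#'
#' @param table A [phenotype_table()].
#' @param trait Trait name.
#' @param baseline_time,target_time Time point labels.
#' @param adjust `"year"` (default) or `"none"`, as in
#'   [phenotypic_correlation()].
#' @return R-squared in `[0, 1]`.
#' @export
baseline_regression_r2 <- function(table, trait, baseline_time, target_time,
                                   adjust = c("year", "none")) {
  adjust <- match.arg(adjust)
  vb <- genotype_values(table, trait, baseline_time, adjust)
  vt <- genotype_values(table, trait, target_time, adjust)
  common <- intersect(names(vb), names(vt))
  if (length(common) < 3) {
    stopf("need >= 3 genotypes with records at both time points (found %d)",
          length(common))
  }
  x <- vb[common]
  if (stats::var(x) == 0) stopf("baseline values are constant; R-squared undefined")
  fit <- stats::lm(vt[common] ~ x)
  summary(fit)$r.squared
}

#' Postharvest descriptive statistics for a trait
#'
#' Per time point: population mean, minimum and maximum; and, against the
#' baseline time point (within genotype, and year for multi-year checks):
#' the mean change, the proportions of genotypes that decreased, increased or
#' tied exactly, and the proportion whose absolute change exceeds
#' `threshold`. Raw rep-averaged values are used by default (population-level
#' description); `adjust = "year"` removes year means first.
#'
#' @param table A [phenotype_table()].
#' @param trait Trait name, observed at two or more time points.
#' @param baseline_time Baseline label, default `"1D"`.
#' @param threshold Absolute-change threshold, default 0 (reported proportion
#'   is then of any strict change).
#' @param adjust `"none"` (default) or `"year"`.
#' @return List with data frames `per_time` (mean/min/max) and `vs_baseline`
#'   (mean_diff, prop_decreased, prop_increased, prop_unchanged,
#'   prop_beyond_threshold, n).
#' @export
postharvest_descriptives <- function(table, trait, baseline_time = "1D",
                                     threshold = 0,
                                     adjust = c("none", "year")) {
  adjust <- match.arg(adjust)
  times_obs <- TIME_LEVELS[TIME_LEVELS %in%
    as.character(unique(table$time_point[table$trait == trait]))]
  if (length(times_obs) < 2) stopf("trait '%s' observed at fewer than 2 time points", trait)
  if (!baseline_time %in% times_obs) {
    stopf("baseline time %s has no records for trait '%s'", baseline_time, trait)
  }
  vals <- lapply(times_obs, function(tt) genotype_values(table, trait, tt, adjust))
  names(vals) <- times_obs
  per_time <- data.frame(
    time_point = times_obs,
    mean = vapply(vals, mean, numeric(1)),
    min = vapply(vals, min, numeric(1)),
    max = vapply(vals, max, numeric(1)),
    n = vapply(vals, length, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  vb <- vals[[baseline_time]]
  later <- setdiff(times_obs, baseline_time)
  vs <- lapply(later, function(tt) {
    vt <- vals[[tt]]
    common <- intersect(names(vb), names(vt))
    ch <- vt[common] - vb[common]
    data.frame(
      time_point = tt,
      mean_diff = mean(ch),
      prop_decreased = mean(ch < 0),
      prop_increased = mean(ch > 0),
      prop_unchanged = mean(ch == 0),
      prop_beyond_threshold = mean(abs(ch) > threshold),
      n = length(ch),
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
  list(per_time = per_time, vs_baseline = do.call(rbind, vs))
}

#' Table of genetic parameters for one trait
#'
#' Convenience wrapper reproducing the usual report for a longitudinal trait:
#' heritability per time point, the interaction likelihood-ratio test against
#' the no-interaction model, and the crossover proportion between the first
#' and last fitted time points.
#'
#' @param pheno A [phenotype_table()].
#' @param grm A [vanraden_grm()] result.
#' @param spec A [model_spec()]; `genetic` must be `"us"`.
#' @param psi_iter Monte-Carlo iterations for the crossover proportion,
#'   default 100000.
#' @param seed Seed for the crossover sampling.
#' @param ... Passed to [fit_longitudinal()].
#' @return List with `fit`, `reduced_fit`, and `table`, a one-row data frame:
#'   `trait`, `h2_<time>` columns, `lrt_p`, `psi`.
#' @export
genetic_parameter_table <- function(pheno, grm, spec, psi_iter = 1e5,
                                    seed = 1L, ...) {
  stopifnot(inherits(spec, "model_spec"))
  fit <- fit_longitudinal(pheno, grm, spec, ...)
  red_spec <- model_spec(spec$trait, spec$time_points, genetic = "common",
                         residual = spec$residual)
  red <- fit_longitudinal(pheno, grm, red_spec, ...)
  lrt <- lrt_interaction(fit, red)
  h2 <- heritability(fit$components)
  tp <- fit$times
  psi <- if (length(tp) >= 2) {
    psi_monte_carlo(fit$blups[fit$rand_ids, , drop = FALSE],
                    tp[1], tp[length(tp)], n_iter = psi_iter, seed = seed)$psi
  } else NA_real_
  row <- data.frame(trait = spec$trait, stringsAsFactors = FALSE)
  for (i in seq_along(tp)) row[[paste0("h2_", tp[i])]] <- h2$h2[i]
  row$lrt_p <- lrt$p_value
  row$psi <- psi
  list(fit = fit, reduced_fit = red, table = row)
}
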