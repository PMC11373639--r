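#' Specification of a longitudinal mixed model
#'
#' Describes one trait's longitudinal GBLUP model: which postharvest time
#' points enter, and the covariance structures for the genetic and residual
#' effects across time points.
#'
#' Genetic structures:
#' * `"us"` — unstructured: a full covariance matrix across time points, one
#'   genetic effect per genotype and time point. This is the complete model
#'   with genotype-by-time interaction.
#' * `"common"` — a single genetic effect per genotype shared by all time
#'   points (equal variances, correlation 1): the reduced model without
#'   interaction, used as the null of the interaction likelihood-ratio test.
#' * `"indep"` — heterogeneous variances, zero genetic correlation between
#'   time points.
#'
#' Residual structures: `"us"` or `"indep"` with the same meanings.
#'
#' @param trait Trait name as it appears in the phenotype table.
#' @param time_points Ordered subset of `1D, 1W, 3W, 7W` (default all).
#' @param genetic One of `"us"`, `"common"`, `"indep"`.
#' @param residual One of `"us"`, `"indep"`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(trait, time_points = TIME_LEVELS,
                       genetic = c("us", "common", "indep"),
                       residual = c("us", "indep")) {
  genetic <- match.arg(genetic)
  residual <- match.arg(residual)
  time_points <- match.arg(time_points, TIME_LEVELS, several.ok = TRUE)
  time_points <- TIME_LEVELS[TIME_LEVELS %in% time_points] # canonical order
  if (length(time_points) < 1) stopf("at least one time point is required")
  structure(list(trait = trait, time_points = time_points,
                 genetic = genetic, residual = residual),
            class = "model_spec")
}

#' Fit the longitudinal GBLUP mixed model by REML
#'
#' Fits, for one trait,
#' \deqn{y = X_1\beta + X_2 t + X_3 g_1 + Z g_2 + e,}
#' where \eqn{\beta} holds a population mean per time point plus year-of-
#' evaluation effects, \eqn{t} the postharvest-time fixed effects (absorbed
#' into the per-time means), \eqn{g_1} fixed effects of the check genotypes
#' connecting years, and \eqn{g_2} the random genetic effects of regular
#' genotypes with \eqn{g_2 \sim MVN(0, \Sigma_t \otimes G)} and
#' \eqn{e \sim MVN(0, \Sigma_e \otimes I)} arranged in (genotype, year)
#' residual units. \eqn{\Sigma_t} and \eqn{\Sigma_e} follow the structures in
#' the [model_spec()].
#'
#' Restricted maximum likelihood estimates are obtained by quasi-Newton
#' maximization over log-Cholesky parameterized covariances (positive
#' semi-definite at every iterate, variances floored at 1e-10), warm-started
#' from phenotypic moment estimates. Technical reps are averaged first;
#' genotypes may have missing records at some time points (the likelihood is
#' record-level). BLUPs (GEBVs) are produced for every genotype in `grm`,
#' including unphenotyped ones, which borrow information through their
#' genomic relationships.
#'
#' @param pheno A [phenotype_table()].
#' @param grm A [vanraden_grm()] result covering at least every phenotyped
#'   non-check genotype.
#' @param spec A [model_spec()].
#' @param tol Convergence tolerance: relative change in the REML
#'   log-likelihood, default `1e-8`.
#' @param max_iter Maximum optimizer iterations, default 200.
#' @param init Optional list with `sigma_t` and `sigma_e` starting matrices.
#' @return An object of class `longitudinal_fit` with elements `spec`, `beta`
#'   (named fixed effects), `vcov_beta`, `blups` (genotype x time GEBV matrix
#'   over all `grm` genotypes), `components` (list with `sigma_t`, `sigma_e`,
#'   class `covariance_components`), `loglik`, `n_records`, `n_params`,
#'   `converged`, `n_iter`.
#' @export
fit_longitudinal <- function(pheno, grm, spec, tol = 1e-8, max_iter = 200L,
                             init = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (!inherits(grm, "genomic_relationship") && !is.matrix(grm)) {
    stopf("grm must be a genomic_relationship or a named square matrix")
  }
  if (is.null(rownames(grm))) stopf("the relationship matrix needs genotype ids as dimnames")
  times <- spec$time_points
  T <- length(times)

  df <- as.data.frame(pheno)
  df <- df[df$trait == spec$trait, , drop = FALSE]
  if (nrow(df) == 0) stopf("trait '%s' not found in the phenotype table", spec$trait)
  df <- df[as.character(df$time_point) %in% times, , drop = FALSE]
  df <- as.data.frame(average_reps(phenotype_table(df)))
  df <- df[!is.na(df$value), , drop = FALSE]
  if (nrow(df) == 0) stopf("no non-missing records for trait '%s'", spec$trait)
  empty <- setdiff(times, unique(as.character(df$time_point)))
  if (length(empty) > 0) {
    stopf("no records at time point(s): %s", paste(empty, collapse = ", "))
  }

  rand_pheno <- unique(df$genotype_id[!df$is_check])
  if (length(rand_pheno) == 0) stopf("no non-check genotypes to model as random")
  miss <- setdiff(rand_pheno, rownames(grm))
  if (length(miss) > 0) {
    stopf("phenotyped non-check genotype(s) missing from the relationship matrix: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  }

  records <- data.frame(
    genotype_id = df$genotype_id,
    year = df$year,
    tidx = match(as.character(df$time_point), times),
    value = df$value,
    is_check = df$is_check,
    stringsAsFactors = FALSE
  )

  X <- build_fixed_design(records, times)
  G_rand <- unclass(grm)[rand_pheno, rand_pheno, drop = FALSE]
  ed <- engine_prepare(records, X$X, G_rand, T)

  if (is.null(init)) init <- moment_init(records, T)
  fit <- engine_reml(ed, spec$genetic, spec$residual,
                     init$sigma_t, init$sigma_e, tol = tol,
                     max_iter = max_iter)

  sigma_t <- fit$sigma_t
  sigma_e <- fit$sigma_e
  dimnames(sigma_t) <- dimnames(sigma_e) <- list(times, times)

  # GEBVs for every genotype in the grm: u_hat = G[, obs] %*% Pmat %*% Sigma_t
  Gfull <- unclass(grm)
  blups <- Gfull[, ed$rand_ids, drop = FALSE] %*% fit$Pmat %*% sigma_t
  colnames(blups) <- times

  beta <- stats::setNames(fit$beta, X$names)
  components <- structure(list(sigma_t = sigma_t, sigma_e = sigma_e),
                          class = "covariance_components")
  structure(list(
    spec = spec, beta = beta, vcov_beta = fit$vcov_beta,
    blups = blups, components = components,
    loglik = fit$loglik, n_records = ed$N, n_params = fit$n_params,
    converged = fit$converged, n_iter = fit$n_iter,
    times = times, rand_ids = ed$rand_ids,
    n_fixed = ed$p, fixed_names = X$names,
    time_cols = seq_len(T),
    year_levels = X$year_levels, check_ids = X$check_ids
  ), class = "longitudinal_fit")
}

# Fixed design: per-time intercepts, year contrasts (years beyond the first),
# and one column per check genotype.
build_fixed_design <- function(records, times) {
  T <- length(times)
  N <- nrow(records)
  Xt <- matrix(0, N, T)
  Xt[cbind(seq_len(N), records$tidx)] <- 1
  nms <- paste0("time_", times)
  year_levels <- sort(unique(records$year))
  Xy <- NULL
  if (length(year_levels) > 1) {
    Xy <- matrix(0, N, length(year_levels) - 1L)
    for (j in seq_along(year_levels)[-1]) {
      Xy[records$year == year_levels[j], j - 1L] <- 1
    }
    nms <- c(nms, paste0("year_", year_levels[-1]))
  }
  check_ids <- sort(unique(records$genotype_id[records$is_check]))
  Xc <- NULL
  if (length(check_ids) > 0) {
    Xc <- matrix(0, N, length(check_ids))
    for (j in seq_along(check_ids)) {
      Xc[records$genotype_id == check_ids[j], j] <- 1
    }
    nms <- c(nms, paste0("check_", check_ids))
  }
  X <- cbind(Xt, Xy, Xc)
  list(X = X, names = nms, year_levels = year_levels, check_ids = check_ids)
}

# Moment-based starting values: split the year-adjusted phenotypic
# covariance across time points 50/50 between genetics and residual.
moment_init <- function(records, T) {
  v <- records$value
  adjkey <- paste(records$year, records$tidx)
  v <- v - stats::ave(v, adjkey)
  gkey <- paste(records$genotype_id, records$year)
  M <- matrix(NA_real_, length(unique(gkey)), T)
  M[cbind(match(gkey, unique(gkey)), records$tidx)] <- v
  C <- suppressWarnings(stats::cov(M, use = "pairwise.complete.obs"))
  tot <- stats::var(v)
  if (!is.finite(tot) || tot <= 0) tot <- 1
  C[!is.finite(C)] <- 0
  diag(C)[diag(C) <= 0] <- tot
  # shrink toward the diagonal for positive definiteness
  C <- 0.8 * C + 0.2 * diag(diag(C), T)
  list(sigma_t = C / 2, sigma_e = C / 2 + diag(0.05 * diag(C), T))
}

#' @export
print.longitudinal_fit <- function(x, ...) {
  cat(sprintf("longitudinal_fit: trait '%s', %d time point(s) [%s]\n",
              x$spec$trait, length(x$times), paste(x$times, collapse = ", ")))
  cat(sprintf("  genetic: %s, residual: %s; %d records, %d genotypes (random)\n",
              x$spec$genetic, x$spec$residual, x$n_records, length(x$rand_ids)))
  cat(sprintf("  REML logLik %.4f (%s, %d evaluations), %d covariance parameter(s)\n",
              x$loglik, if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$n_params))
  h2 <- tryCatch(heritability(x$components), error = function(e) NULL)
  if (!is.null(h2)) {
    cat("  h2 per time point:",
        paste(sprintf("%s=%.2f", x$times, h2$h2), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract genomic estimated breeding values
#'
#' Returns the GEBV matrix rows for the requested genotypes. All genotypes of
#' the relationship matrix used in the fit are available: phenotyped ones get
#' their BLUPs, unphenotyped ones are predicted through their genomic
#' relationship with the phenotyped set (for a genotype with no records this
#' equals `G[new, obs] %*% solve(G[obs, obs]) %*% u[obs]`).
#'
#' @param fit A [fit_longitudinal()] result.
#' @param genotype_ids Character vector of genotype ids.
#' @return Matrix genotypes x time points of GEBVs.
#' @export
predict_gebv <- function(fit, genotype_ids) {
  stopifnot(inherits(fit, "longitudinal_fit"))
  genotype_ids <- as.character(genotype_ids)
  miss <- setdiff(genotype_ids, rownames(fit$blups))
  if (length(miss) > 0) {
    stopf("unknown genotype id(s): %s", paste(utils::head(miss, 5), collapse = ", "))
  }
  fit$blups[genotype_ids, , drop = FALSE]
}

#' Bayesian information criterion of a longitudinal fit
#'
#' `BIC = -2 logL + k log(n)` with `k` the number of estimated (co)variance
#' parameters and `n` the number of phenotypic records entering the fit
#' (after rep averaging). REML information criteria differ between software
#' dialects in both `k` and `n`; this choice is documented and used
#' consistently, which is what model comparison requires.
#'
#' @param fit A [fit_longitudinal()] result.
#' @return Numeric BIC value (smaller is better).
#' @export
bic <- function(fit) {
  stopifnot(inherits(fit, "longitudinal_fit"))
  if (!fit$converged) warnf("BIC computed from a non-converged fit")
  -2 * fit$loglik + fit$n_params * log(fit$n_records)
}

#' Wald test of the postharvest-time fixed effect
#'
#' Tests equality of the per-time-point population means with a Wald
#' chi-square on the time contrasts (conditional on all other fixed effects),
#' using the REML estimate of `var(beta)`.
#'
#' @param fit A [fit_longitudinal()] result with at least two time points.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
wald_time_effect <- function(fit) {
  stopifnot(inherits(fit, "longitudinal_fit"))
  T <- length(fit$times)
  if (T < 2) stopf("the time-effect Wald test needs at least two time points")
  p <- length(fit$beta)
  L <- matrix(0, T - 1L, p)
  for (i in seq_len(T - 1L)) {
    L[i, 1L] <- -1
    L[i, i + 1L] <- 1
  }
  lb <- drop(L %*% fit$beta)
  Vl <- L %*% fit$vcov_beta %*% t(L)
  stat <- drop(crossprod(lb, solve(Vl, lb)))
  list(statistic = stat, df = T - 1L,
       p_value = stats::pchisq(stat, df = T - 1L, lower.tail = FALSE))
}

#' Likelihood-ratio test for the genotype-by-time interaction
#'
#' Compares the complete longitudinal model (genetic effects specific to each
#' time point, unstructured covariance) against the reduced model with a
#' single genetic effect common to all time points (no interaction). The
#' statistic `2 (logL_full - logL_reduced)` is referred to a chi-square with
#' degrees of freedom equal to the difference in covariance-parameter counts.
#' Because the null pins parameters at a boundary, the nominal-df reference is
#' an approximation; see the package vignette.
#'
#' @param full Fit with `genetic = "us"`.
#' @param reduced Fit with `genetic = "common"` on the same data and fixed
#'   effects.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt_interaction <- function(full, reduced) {
  stopifnot(inherits(full, "longitudinal_fit"), inherits(reduced, "longitudinal_fit"))
  if (reduced$spec$genetic != "common") {
    stopf("the reduced model must use genetic = 'common' (no interaction)")
  }
  same <- identical(full$spec$trait, reduced$spec$trait) &&
    identical(full$times, reduced$times) &&
    identical(full$spec$residual, reduced$spec$residual) &&
    full$n_records == reduced$n_records
  if (!same) stopf("models are not nested fits of the same data")
  df <- full$n_params - reduced$n_params
  if (df <= 0) stopf("the full model has no extra covariance parameters")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}
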