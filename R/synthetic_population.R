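#' Simulation configuration for a synthetic tetraploid breeding population
#'
#' Defines the data-generating conditions for the synthetic population:
#' population size, check genotypes replicated across years (augmented
#' design), marker panel, per-time-point heritability targets, genetic and
#' residual correlation across the four postharvest time points, year effects
#' and technical reps. Defaults emulate the design of a southern highbush
#' blueberry advanced-selection trial: 588 genotypes of which 16 are checks
#' evaluated in every one of 3 years, tetraploid dosages, time points
#' 1D/1W/3W/7W with genetic correlations decaying with time lag.
#'
#' @param n_genotypes Total genotypes (default 588).
#' @param n_checks Check genotypes present in every year (default 16).
#' @param n_years Evaluation years (default 3); non-checks are spread
#'   uniformly, one year each.
#' @param n_markers Markers on the panel (default 2000).
#' @param ploidy Default 4 (autotetraploid).
#' @param maf_range Allele-frequency range for simulated markers,
#'   default `c(0.05, 0.5)`.
#' @param n_qtl Markers with nonzero effect per trait (default 200).
#' @param time_points Time point labels, default all of `1D, 1W, 3W, 7W`.
#' @param h2_target Per-time-point narrow-sense heritability targets,
#'   recycled to `length(time_points)`; default 0.5 at every time point.
#' @param genetic_corr_lag Genetic correlation between time points at lag 1,
#'   2, 3; default `c(0.9, 0.7, 0.4)`.
#' @param residual_corr_lag Residual correlation by lag; fruit measured at
#'   different time points comes from distinct clamshell samples of the same
#'   harvest, so a modest decay is used, default `c(0.25, 0.1, 0)`.
#' @param residual_var Residual variance per time point, default 1.
#' @param year_effect_sd SD of the year fixed effects, default 0.5.
#' @param time_effect_step Increment of the population mean per successive
#'   time point (default 0.5 residual-SD units); set 0 for a null time effect.
#' @param n_reps Technical reps per record (default 2); rep noise SD is 10%
#'   of the residual SD and exists only to exercise rep averaging.
#' @param trait Trait name used in the output table, default `"firmness"`.
#' @param seed Integer seed for all randomness.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genotypes = 588L, n_checks = 16L, n_years = 3L,
                              n_markers = 2000L, ploidy = 4L,
                              maf_range = c(0.05, 0.5), n_qtl = 200L,
                              time_points = TIME_LEVELS,
                              h2_target = 0.5,
                              genetic_corr_lag = c(0.9, 0.7, 0.4),
                              residual_corr_lag = c(0.25, 0.1, 0),
                              residual_var = 1,
                              year_effect_sd = 0.5,
                              time_effect_step = 0.5,
                              n_reps = 2L,
                              trait = "firmness",
                              seed = 1L) {
  time_points <- match.arg(time_points, TIME_LEVELS, several.ok = TRUE)
  nt <- length(time_points)
  h2 <- rep_len(h2_target, nt)
  if (any(h2 <= 0) || any(h2 >= 1)) stopf("h2 targets must lie strictly in (0, 1)")
  if (n_checks >= n_genotypes) stopf("n_checks must be smaller than n_genotypes")
  if (n_qtl > n_markers) stopf("n_qtl cannot exceed n_markers")
  rv <- rep_len(residual_var, nt)
  sigma_e <- lag_corr_matrix(nt, residual_corr_lag) * tcrossprod(sqrt(rv))
  gv <- h2 / (1 - h2) * rv
  sigma_t <- lag_corr_matrix(nt, genetic_corr_lag) * tcrossprod(sqrt(gv))
  if (!is_psd(sigma_t) || !is_psd(sigma_e)) {
    stopf("target genetic/residual covariance matrices must be positive semi-definite")
  }
  structure(list(
    n_genotypes = as.integer(n_genotypes), n_checks = as.integer(n_checks),
    n_years = as.integer(n_years), n_markers = as.integer(n_markers),
    ploidy = as.integer(ploidy), maf_range = maf_range,
    n_qtl = as.integer(n_qtl), time_points = time_points,
    h2_target = h2, sigma_t = sigma_t, sigma_e = sigma_e,
    year_effect_sd = year_effect_sd, time_effect_step = time_effect_step,
    n_reps = as.integer(n_reps),
    trait = trait, seed = as.integer(seed)
  ), class = "simulation_config")
}

# Correlation matrix with entries determined by |i - j| lag.
lag_corr_matrix <- function(nt, corr_by_lag) {
  if (nt == 1) return(matrix(1, 1, 1))
  corr_by_lag <- rep_len(corr_by_lag, nt - 1)
  m <- diag(nt)
  for (lag in seq_len(nt - 1)) {
    for (i in seq_len(nt - lag)) {
      m[i, i + lag] <- m[i + lag, i] <- corr_by_lag[lag]
    }
  }
  m
}

#' Simulate a tetraploid allele-dosage matrix
#'
#' Marker `j` gets an allele frequency drawn uniformly from the configured
#' range; dosages are i.i.d. `Binomial(ploidy, p_j)` across genotypes
#' (polysomic Hardy-Weinberg equilibrium, no linkage disequilibrium and no
#' family structure, mirroring a diverse multi-family breeding population).
#'
#' @param config A [simulation_config()].
#' @return A [dosage_matrix()] with attribute `allele_freq` (the true
#'   frequencies used).
#' @export
simulate_dosages <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  p <- stats::runif(config$n_markers, config$maf_range[1], config$maf_range[2])
  m <- matrix(
    stats::rbinom(config$n_genotypes * config$n_markers,
                  size = config$ploidy,
                  prob = rep(p, each = config$n_genotypes)),
    nrow = config$n_genotypes, ncol = config$n_markers
  )
  dm <- dosage_matrix(m,
                      genotype_ids = sprintf("G%04d", seq_len(config$n_genotypes)),
                      marker_ids = sprintf("M%05d", seq_len(config$n_markers)),
                      ploidy = config$ploidy)
  attr(dm, "allele_freq") <- p
  dm
}

#' Simulate longitudinal phenotypes with known truth
#'
#' Generates an additive longitudinal trait on top of a simulated (or
#' supplied) dosage matrix. A random subset of `n_qtl` markers receives
#' effect vectors across time points drawn from a multivariate normal whose
#' covariance is the target genetic covariance scaled by the panel's realized
#' dosage variance, so breeding values `u[i, t] = sum_j w[i, j] alpha[j, t]`
#' hit the target heritabilities in expectation. Phenotypes add a time-point
#' mean, a year effect, and residuals drawn per genotype-year from the target
#' residual covariance; technical reps add small i.i.d. noise (10% of the
#' residual SD). The first `n_checks` genotypes are checks and appear in every
#' year; the rest are assigned one year each, uniformly.
#'
#' @param dosages A [dosage_matrix()], typically from [simulate_dosages()].
#' @param config A [simulation_config()].
#' @return A list with `pheno` (a [phenotype_table()]) and `truth`, a list
#'   holding the true marker effects, true breeding values (genotype x time),
#'   true covariance targets, realized heritabilities and genetic
#'   correlations computed from the generated sample, and the year effects.
#' @export
simulate_phenotypes <- function(dosages, config) {
  stopifnot(inherits(dosages, "dosage_matrix"), inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  nt <- length(config$time_points)
  n <- nrow(dosages)
  ids <- rownames(dosages)

  # marker effects at QTL, correlated across time points
  qtl <- sort(sample.int(ncol(dosages), config$n_qtl))
  M <- unclass(dosages)[, qtl, drop = FALSE]
  storage.mode(M) <- "double"
  p_hat <- colMeans(M) / config$ploidy
  W <- sweep(M, 2, config$ploidy * p_hat, "-")
  # scale so E[var(u_t)] matches the target genetic variance
  dose_var <- sum(config$ploidy * p_hat * (1 - p_hat))
  sigma_alpha <- config$sigma_t / dose_var
  alpha <- rmvn(config$n_qtl, sigma_alpha)
  u <- W %*% alpha # n x nt true breeding values
  colnames(u) <- config$time_points
  rownames(u) <- ids

  # design: checks in every year, others one year each
  is_check <- seq_len(n) <= config$n_checks
  years <- 2000L + seq_len(config$n_years)
  year_effect <- stats::setNames(stats::rnorm(config$n_years, 0, config$year_effect_sd),
                                 years)
  if (config$n_years == 1) year_effect[] <- 0
  year_of <- sample(rep_len(years, n - config$n_checks))
  time_mean <- stats::setNames(seq_len(nt) * config$time_effect_step,
                               config$time_points)

  rows <- vector("list", n)
  rep_sd <- 0.1 * sqrt(mean(diag(config$sigma_e)))
  for (i in seq_len(n)) {
    yrs <- if (is_check[i]) years else year_of[i - config$n_checks]
    per_year <- lapply(yrs, function(yy) {
      e <- drop(rmvn(1, config$sigma_e))
      base <- time_mean + year_effect[as.character(yy)] + u[i, ] + e
      data.frame(
        genotype_id = ids[i], year = yy,
        time_point = rep(config$time_points, each = config$n_reps),
        trait = config$trait,
        value = rep(base, each = config$n_reps) +
          stats::rnorm(nt * config$n_reps, 0, rep_sd),
        is_check = is_check[i],
        rep = rep(seq_len(config$n_reps), nt),
        stringsAsFactors = FALSE
      )
    })
    rows[[i]] <- do.call(rbind, per_year)
  }
  pheno <- phenotype_table(do.call(rbind, rows))

  gvar <- apply(u, 2, stats::var)
  realized_h2 <- gvar / (gvar + diag(config$sigma_e))
  truth <- list(
    qtl_markers = colnames(dosages)[qtl],
    marker_effects = alpha,
    breeding_values = u,
    sigma_t_target = config$sigma_t,
    sigma_e = config$sigma_e,
    realized_h2 = realized_h2,
    realized_genetic_corr = stats::cor(u),
    year_effects = year_effect,
    time_means = time_mean
  )
  list(pheno = pheno, truth = truth)
}

#' Drop trait-by-time blocks to emulate single-time traits
#'
#' Optional missingness injector: keeps a trait's records only at the listed
#' time points, emulating traits measured at a single storage stage (water
#' loss at 7W only, pedicel scar at 1D only).
#'
#' @param table A [phenotype_table()].
#' @param trait Trait name to restrict.
#' @param keep_times Time point labels to keep for that trait.
#' @return A [phenotype_table()].
#' @export
restrict_trait_times <- function(table, trait, keep_times) {
  keep_times <- match.arg(keep_times, TIME_LEVELS, several.ok = TRUE)
  drop <- table$trait == trait & !(as.character(table$time_point) %in% keep_times)
  phenotype_table(as.data.frame(table)[!drop, , drop = FALSE])
}
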