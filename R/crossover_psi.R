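#' Crossover interaction proportion, Monte-Carlo estimate
#'
#' The crossover statistic psi quantifies genotype-by-time interaction as the
#' proportion of genotype pairs whose ranking reverses between two storage
#' time points: a pair (i, i') is a crossover when
#' `(u[i, j] - u[i', j])` and `(u[i, j'] - u[i', j'])` have strictly opposite
#' signs. Ties (either difference exactly zero) count as non-crossover, since
#' the defining conditions are strict inequalities. Pairs are sampled
#' uniformly with replacement over unordered pairs; for true breeding values
#' that are bivariate normal with correlation rho, the population value is
#' `arccos(rho) / pi`.
#'
#' @param blups Numeric matrix, genotypes x time points (e.g. the `blups`
#'   element of a [fit_longitudinal()] result), with column names.
#' @param time_i,time_j Column labels (or indices) of the two time points.
#' @param n_iter Number of sampled pairs, default 100000.
#' @param seed Integer seed making the sampling reproducible.
#' @return List of class `crossover_result`: `time_pair`, `psi`, `n_iter`,
#'   `seed`, `method = "monte_carlo"`.
#' @export
psi_monte_carlo <- function(blups, time_i, time_j, n_iter = 1e5, seed = 1L) {
  u <- psi_columns(blups, time_i, time_j)
  n <- nrow(u)
  if (n_iter < 1) stopf("n_iter must be >= 1")
  set.seed(as.integer(seed))
  i <- sample.int(n, n_iter, replace = TRUE)
  j <- sample.int(n - 1L, n_iter, replace = TRUE)
  j <- j + (j >= i)
  d1 <- u[i, 1] - u[j, 1]
  d2 <- u[i, 2] - u[j, 2]
  psi <- mean(d1 * d2 < 0)
  structure(list(time_pair = c(time_i, time_j), psi = psi,
                 n_iter = as.integer(n_iter), seed = as.integer(seed),
                 method = "monte_carlo"),
            class = "crossover_result")
}

#' Crossover interaction proportion, exact enumeration
#'
#' Exact version of [psi_monte_carlo()]: evaluates the crossover condition on
#' all `choose(n, 2)` unordered genotype pairs.
#'
#' @inheritParams psi_monte_carlo
#' @return List of class `crossover_result` with `method = "exact"`.
#' @export
psi_exact <- function(blups, time_i, time_j) {
  u <- psi_columns(blups, time_i, time_j)
  n <- nrow(u)
  d1 <- outer(u[, 1], u[, 1], "-")
  d2 <- outer(u[, 2], u[, 2], "-")
  upper <- upper.tri(d1)
  psi <- sum(d1[upper] * d2[upper] < 0) / choose(n, 2)
  structure(list(time_pair = c(time_i, time_j), psi = psi,
                 n_iter = NA_integer_, seed = NA_integer_, method = "exact"),
            class = "crossover_result")
}

psi_columns <- function(blups, time_i, time_j) {
  blups <- as.matrix(blups)
  if (nrow(blups) < 2) stopf("at least 2 genotypes are required")
  get_col <- function(tt) {
    if (is.character(tt)) {
      if (!tt %in% colnames(blups)) stopf("time point '%s' not in the BLUP matrix", tt)
      blups[, tt]
    } else blups[, tt]
  }
  u <- cbind(get_col(time_i), get_col(time_j))
  if (anyNA(u)) stopf("BLUPs contain missing values")
  u
}

#' @export
print.crossover_result <- function(x, ...) {
  cat(sprintf("psi(%s, %s) = %.4f [%s%s]\n",
              x$time_pair[1], x$time_pair[2], x$psi, x$method,
              if (x$method == "monte_carlo")
                sprintf(", %d iterations, seed %d", x$n_iter, x$seed) else ""))
  invisible(x)
}
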