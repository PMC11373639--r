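#' Postharvest time point labels, in storage order
#'
#' The canonical evaluation schedule: 1 day, 1 week, 3 weeks and 7 weeks of
#' cold storage. All phenotype tables and model specifications use this
#' ordering.
#'
#' @format Character vector of length 4.
#' @export
TIME_LEVELS <- c("1D", "1W", "3W", "7W")

# Coerce a vector of time labels to an ordered factor, erroring on unknown
# labels (e.g. "2W") with the allowed set in the message.
as_time_point <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), TIME_LEVELS)
  if (length(bad) > 0) {
    stop(sprintf(
      "unknown time point label(s): %s; allowed labels are: %s",
      paste(bad, collapse = ", "), paste(TIME_LEVELS, collapse = ", ")
    ), call. = FALSE)
  }
  factor(x, levels = TIME_LEVELS, ordered = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Deterministic derivation of sub-seeds from one master seed, so that
# repeated stages (CV repeats, permutations) are independent streams yet
# reproducible from a single integer. Kept below 2^31 - 1.
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Multivariate normal draws via Cholesky (n x d), mean zero.
rmvn <- function(n, sigma) {
  d <- nrow(sigma)
  L <- chol(sigma + diag(1e-12, d))
  matrix(stats::rnorm(n * d), n, d) %*% L
}

is_psd <- function(m, tol = 1e-8) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev >= -tol * max(abs(ev), 1))
}
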