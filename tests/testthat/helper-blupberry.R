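# Shared helpers: small data builders and independent reference
# implementations used as oracles. Nothing here calls the engine internals it
# is used to check.

# -- toy phenotype table ------------------------------------------------------
toy_pheno <- function() {
  phenotype_table(data.frame(
    genotype_id = rep(c("g1", "g2"), each = 4),
    year = 2021L,
    time_point = rep(c("1D", "1W", "3W", "7W"), 2),
    trait = "firmness",
    value = c(200, 210, 205, 150, 180, 182, 181, 178),
    is_check = FALSE,
    rep = 1L
  ))
}

# -- naive dense-V restricted log-likelihood ---------------------------------
# Builds V entry by entry from the model definition: genetic covariance
# Sigma_t[t, t'] * G[g, g'] between any two records of random genotypes, plus
# residual covariance Sigma_e[t, t'] within a (genotype, year) unit. Used to
# check the structured engine.
dense_reml_loglik <- function(St, Se, records, X, G_rand) {
  N <- nrow(records)
  p <- ncol(X)
  V <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      gi <- records$genotype_id[i]; gj <- records$genotype_id[j]
      if (!records$is_check[i] && !records$is_check[j]) {
        V[i, j] <- V[i, j] + St[records$tidx[i], records$tidx[j]] * G_rand[gi, gj]
      }
      if (gi == gj && records$year[i] == records$year[j]) {
        V[i, j] <- V[i, j] + Se[records$tidx[i], records$tidx[j]]
      }
    }
  }
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% records$value)
  r <- records$value - X %*% beta
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtVX)$modulus +
                       t(r) %*% Vi %*% r + (N - p) * log(2 * pi)))
}

# Random small model instances in three configurations: fully balanced;
# CV2-like (some genotypes keep a single time point); messy (random missing
# records, one multi-year genotype, check genotypes).
make_engine_instance <- function(seed, n_g = 8, T = 3, kind = "balanced") {
  set.seed(seed)
  ids <- paste0("g", seq_len(n_g))
  G <- crossprod(matrix(rnorm(n_g * n_g), n_g)) / n_g + diag(0.05, n_g)
  dimnames(G) <- list(ids, ids)
  recs <- expand.grid(genotype_id = ids, tidx = seq_len(T),
                      stringsAsFactors = FALSE)
  recs$year <- 2001L
  recs$is_check <- FALSE
  if (kind == "cv2like") {
    drop <- recs$genotype_id %in% ids[(n_g - 2):n_g] & recs$tidx > 1
    recs <- recs[!drop, ]
  } else if (kind == "messy") {
    set.seed(seed + 1)
    recs <- recs[stats::runif(nrow(recs)) > 0.25, ]
    extra <- recs[recs$genotype_id == ids[1], ]
    extra$year <- 2002L
    recs <- rbind(recs, extra)
    chk <- expand.grid(genotype_id = c("c1", "c2"), tidx = seq_len(T),
                       stringsAsFactors = FALSE)
    chk <- rbind(chk, chk)
    chk$year <- rep(c(2001L, 2002L), each = nrow(chk) / 2)
    chk$is_check <- TRUE
    recs <- rbind(recs, chk)
  }
  recs$value <- stats::rnorm(nrow(recs), recs$tidx * 0.3)
  Xt <- matrix(0, nrow(recs), T)
  Xt[cbind(seq_len(nrow(recs)), recs$tidx)] <- 1
  X <- Xt
  if (length(unique(recs$year)) > 1) X <- cbind(X, as.numeric(recs$year == 2002L))
  for (cc in unique(recs$genotype_id[recs$is_check])) {
    X <- cbind(X, as.numeric(recs$genotype_id == cc))
  }
  list(records = recs, X = X, G = G, T = T)
}

rand_cov <- function(T, seed) {
  set.seed(seed)
  A <- matrix(stats::rnorm(T * T), T)
  crossprod(A) / T + diag(0.2, T)
}

# -- brute-force REML maximizer for tiny two-time instances ------------------
# Independent of the package's engine: dense V, generic optimizer over the
# six covariance parameters (log-Cholesky of 2x2 Sigma_t and Sigma_e).
oracle_tiny_loglik <- function(theta, y, X, Gm, tidx, gidx) {
  L1 <- matrix(0, 2, 2); L1[lower.tri(L1, diag = TRUE)] <- theta[1:3]
  diag(L1) <- exp(diag(L1)); St <- tcrossprod(L1)
  L2 <- matrix(0, 2, 2); L2[lower.tri(L2, diag = TRUE)] <- theta[4:6]
  diag(L2) <- exp(diag(L2)); Se <- tcrossprod(L2)
  N <- length(y); p <- ncol(X)
  V <- St[tidx, tidx] * Gm[gidx, gidx] + Se[tidx, tidx] * outer(gidx, gidx, "==")
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-1e10)
  Vi <- chol2inv(ch)
  XtVX <- crossprod(X, Vi %*% X)
  beta <- solve(XtVX, crossprod(X, Vi %*% y))
  r <- y - X %*% beta
  as.numeric(-0.5 * (2 * sum(log(diag(ch))) + determinant(XtVX)$modulus +
                       t(r) %*% Vi %*% r + (N - p) * log(2 * pi)))
}

oracle_tiny_max <- function(y, X, Gm, tidx, gidx, n_starts = 3) {
  vals <- c()
  for (s in seq_len(n_starts)) {
    set.seed(1000 + s)
    th0 <- if (s == 1) rep(c(log(stats::sd(y) / 1.5), 0, log(stats::sd(y) / 1.5)), 2)
           else stats::rnorm(6, 0, 0.7)
    o <- tryCatch(
      stats::optim(th0, function(th) -oracle_tiny_loglik(th, y, X, Gm, tidx, gidx),
                   method = "BFGS", control = list(maxit = 300, reltol = 1e-13)),
      error = function(e) NULL)
    if (is.null(o)) next
    o2 <- stats::optim(o$par,
                       function(th) -oracle_tiny_loglik(th, y, X, Gm, tidx, gidx),
                       method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-13))
    vals <- c(vals, -o$value, -o2$value)
  }
  max(vals)
}

# Simulate a tiny two-time-point dataset plus its relationship matrix.
tiny_two_time_instance <- function(seed) {
  set.seed(seed)
  n <- sample(6:10, 1)
  ids <- paste0("g", seq_len(n))
  dos <- dosage_matrix(matrix(stats::rbinom(n * 60, 4, 0.4), n, 60), ids,
                       paste0("m", seq_len(60)))
  G <- vanraden_grm(dos, ridge = 1e-3)
  St <- crossprod(matrix(stats::rnorm(4), 2)) / 2 + diag(0.3, 2)
  Se <- crossprod(matrix(stats::rnorm(4), 2)) / 2 + diag(0.3, 2)
  uv <- matrix(stats::rnorm(2 * n), 1) %*% chol(kronecker(St, unclass(G)) +
                                                  diag(1e-10, 2 * n))
  um <- matrix(uv, n, 2)
  e <- matrix(stats::rnorm(n * 2), n) %*% chol(Se)
  ph <- phenotype_table(data.frame(
    genotype_id = rep(ids, each = 2), year = 2001L,
    time_point = rep(c("1D", "1W"), n), trait = "x",
    value = as.numeric(t(um + e)) + rep(c(0.2, 0.5), n),
    is_check = FALSE, rep = 1L))
  list(pheno = ph, grm = G, ids = ids)
}

# Reduced-size synthetic population for unit tests.
quick_sim <- function(seed = 1L, n_genotypes = 80L, n_checks = 4L,
                      n_markers = 150L, n_qtl = 60L, ...) {
  cfg <- simulation_config(n_genotypes = n_genotypes, n_checks = n_checks,
                           n_markers = n_markers, n_qtl = n_qtl,
                           seed = seed, ...)
  dos <- simulate_dosages(cfg)
  sim <- simulate_phenotypes(dos, cfg)
  list(config = cfg, dosages = dos, pheno = sim$pheno, truth = sim$truth,
       grm = vanraden_grm(dos))
}
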