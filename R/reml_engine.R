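# Internal REML engine for the longitudinal GBLUP model
#
#   y = X beta + Z u + e,   u ~ N(0, Sigma_t (x) G),   e ~ N(0, R),
#
# where u stacks one genetic effect per (random genotype, time point), R is
# block diagonal with Sigma_e[S_u, S_u] per (genotype, year) unit, and checks
# enter X as fixed effects (their records carry residual covariance only).
#
# The restricted log-likelihood is evaluated exactly but never materializes
# V. Records are split into three parts:
#   * core    — random genotypes with a single unit observed at the modal
#               time pattern S. After rotating the genotype dimension by the
#               eigenvectors of G_core and the time dimension by the
#               generalized eigenvectors of (Sigma_t[S,S], Sigma_e[S,S]),
#               V_core is diagonal: entries 1 + d_i * lambda_s.
#   * extras  — random genotypes with any other record pattern (e.g. CV2
#               test genotypes keeping a single time point). Handled exactly
#               through the Schur complement Q of the core block; the
#               core-extras cross-covariance is separable
#               (G[g, j] * Sigma_t[t, t']), which keeps Q cheap.
#   * checks  — fixed-effect genotypes; independent residual blocks.
#
# Covariances are parameterized by log-Cholesky factors (PSD by
# construction, diagonals floored); the REML log-likelihood is maximized
# with L-BFGS-B using analytic gradients (exact in all three parts; verified
# against numerical differentiation in the test suite).

LOG_SD_FLOOR <- 0.5 * log(1e-10) # variance floor 1e-10
LOG_SD_CEIL <- 0.5 * log(1e12)

n_cov_params <- function(type, T) {
  switch(type,
         us = T * (T + 1L) / 2L,
         indep = T,
         common = 1L,
         stopf("unknown covariance structure '%s'", type))
}

# lower-triangular index order (column-major) used for "us" parameters
lowertri_idx <- function(T) which(lower.tri(diag(T), diag = TRUE))

theta_to_sigma <- function(theta, type, T) {
  switch(type,
    us = {
      L <- matrix(0, T, T)
      L[lowertri_idx(T)] <- theta
      diag(L) <- exp(diag(L))
      tcrossprod(L)
    },
    indep = diag(exp(2 * theta), T),
    common = matrix(exp(2 * theta), T, T)
  )
}

# Chain rule from the full-matrix gradient dl/dSigma (symmetric, "free
# entries" convention) to the unconstrained parameters.
sigma_grad_chain <- function(Gm, theta, type, T) {
  switch(type,
    us = {
      L <- matrix(0, T, T)
      L[lowertri_idx(T)] <- theta
      diag(L) <- exp(diag(L))
      dL <- 2 * Gm %*% L
      diag(dL) <- diag(dL) * diag(L)
      dL[lowertri_idx(T)]
    },
    indep = 2 * diag(Gm) * exp(2 * theta),
    common = 2 * exp(2 * theta) * sum(Gm)
  )
}

sigma_to_theta <- function(Sigma, type, T) {
  switch(type,
    us = {
      L <- t(chol(Sigma + diag(1e-8 * mean(diag(Sigma)) + 1e-12, T)))
      M <- L
      diag(M) <- log(pmax(diag(L), 1e-8))
      M[lowertri_idx(T)]
    },
    indep = 0.5 * log(pmax(diag(Sigma), 1e-10)),
    common = 0.5 * log(max(mean(Sigma), 1e-10))
  )
}

theta_bounds <- function(type, T) {
  n <- n_cov_params(type, T)
  lower <- rep(-Inf, n)
  upper <- rep(Inf, n)
  diag_pos <- switch(type,
                     us = cumsum(c(1, rev(seq_len(T - 1) + 1))[seq_len(T)]),
                     indep = seq_len(T),
                     common = 1L)
  lower[diag_pos] <- LOG_SD_FLOOR
  upper[diag_pos] <- LOG_SD_CEIL
  list(lower = lower, upper = upper, diag_pos = diag_pos)
}

pad_T <- function(M, S, T) {
  out <- matrix(0, T, T)
  out[S, S] <- M
  out
}

# contract a (T*p1) x (T*p1) block tensor (index (a, c): a fastest) with a
# p x p weight matrix over the column-block indices -> T x T
contract_blocks <- function(M, W, T, p1) {
  p <- nrow(W)
  A <- array(M, c(T, p1, T, p1))
  A <- A[, seq_len(p), , seq_len(p), drop = FALSE]
  A <- aperm(A, c(1, 3, 2, 4))
  matrix(matrix(A, T * T, p * p) %*% as.vector(W), T, T)
}

# ---------------------------------------------------------------------------
# engine data preparation

# records: data.frame(genotype_id, year, tidx, value, is_check)
# X: N x p fixed-effect design (rows aligned with records)
# G_rand: relationship matrix over all phenotyped non-check genotypes
engine_prepare <- function(records, X, G_rand, T) {
  N <- nrow(records)
  p <- ncol(X)
  p1 <- p + 1L
  Z <- cbind(X, records$value)

  unit_key <- paste(records$genotype_id, records$year, sep = "\r")
  unit_id <- match(unit_key, unique(unit_key))

  is_rand <- !records$is_check
  rand_rows <- which(is_rand)
  check_rows <- which(!is_rand)

  # record pattern per random genotype; multi-unit genotypes go to extras
  rg <- records$genotype_id[rand_rows]
  rg_ids <- unique(rg)
  pat_of <- vapply(rg_ids, function(g) {
    rows <- rand_rows[rg == g]
    if (length(unique(unit_id[rows])) > 1L) return("")
    paste(sort(records$tidx[rows]), collapse = ",")
  }, character(1))
  pats <- pat_of[pat_of != ""]
  modal_pat <- if (length(pats)) names(sort(table(pats), decreasing = TRUE))[1] else ""
  core_ids <- rg_ids[pat_of == modal_pat & modal_pat != ""]
  extra_ids <- setdiff(rg_ids, core_ids)

  mA <- length(core_ids)
  S <- if (mA > 0) as.integer(strsplit(modal_pat, ",")[[1]]) else integer(0)
  Ts <- length(S)

  core <- NULL
  if (mA > 0) {
    rows_core <- rand_rows[rg %in% core_ids]
    gi <- match(records$genotype_id[rows_core], core_ids)
    si <- match(records$tidx[rows_core], S)
    eg <- eigen(unclass(G_rand)[core_ids, core_ids, drop = FALSE], symmetric = TRUE)
    if (min(eg$values) < -1e-6 * max(abs(eg$values))) {
      stopf("relationship matrix is not positive semi-definite")
    }
    U <- eg$vectors
    d <- pmax(eg$values, 0)
    Zt <- vector("list", p1)
    for (c in seq_len(p1)) {
      M <- matrix(0, mA, Ts)
      M[cbind(gi, si)] <- Z[rows_core, c]
      Zt[[c]] <- crossprod(U, M)
    }
    core <- list(ids = core_ids, S = S, Ts = Ts, U = U, d = d, Zt = Zt)
  }

  extras <- NULL
  bG <- length(extra_ids)
  if (bG > 0) {
    rows_ex <- rand_rows[rg %in% extra_ids]
    b <- length(rows_ex)
    ex_g <- match(records$genotype_id[rows_ex], extra_ids)
    ex_t <- records$tidx[rows_ex]
    ex_unit <- match(unit_id[rows_ex], unique(unit_id[rows_ex]))
    Gee <- unclass(G_rand)[extra_ids, extra_ids, drop = FALSE]
    Hge <- if (mA > 0) {
      crossprod(core$U, unclass(G_rand)[core_ids, extra_ids, drop = FALSE])
    } else matrix(0, 0, bG)
    extras <- list(
      ids = extra_ids, b = b, g = ex_g, t = ex_t, unit = ex_unit,
      ZB = Z[rows_ex, , drop = FALSE],
      Gee = Gee, Gee_rec = Gee[ex_g, ex_g, drop = FALSE],
      Hge = Hge, Hg = Hge[, ex_g, drop = FALSE],
      same_unit = outer(ex_unit, ex_unit, "=="),
      ut = sort(unique(ex_t))
    )
  }

  checks <- list()
  if (length(check_rows) > 0) {
    cu <- unit_id[check_rows]
    cu_ids <- unique(cu)
    pat <- vapply(cu_ids, function(u) {
      paste(sort(records$tidx[check_rows[cu == u]]), collapse = ",")
    }, character(1))
    for (pp in unique(pat)) {
      us_g <- cu_ids[pat == pp]
      Sc <- as.integer(strsplit(pp, ",")[[1]])
      nu <- length(us_g)
      rows_g <- check_rows[cu %in% us_g]
      ui <- match(cu[cu %in% us_g], us_g)
      si <- match(records$tidx[rows_g], Sc)
      Zc <- vector("list", p1)
      for (c in seq_len(p1)) {
        M <- matrix(0, nu, length(Sc))
        M[cbind(ui, si)] <- Z[rows_g, c]
        Zc[[c]] <- M
      }
      checks[[length(checks) + 1L]] <- list(S = Sc, nu = nu, Zc = Zc)
    }
  }

  list(T = T, N = N, p = p, p1 = p1,
       core = core, extras = extras, checks = checks,
       rand_ids = c(core_ids, extra_ids))
}

# ---------------------------------------------------------------------------
# likelihood evaluation: all intermediates for one (Sigma_t, Sigma_e)

engine_eval <- function(St, Se, ed) {
  T <- ed$T; p <- ed$p; p1 <- ed$p1
  CP <- matrix(0, p1, p1)
  logdetV <- 0
  ev <- list(St = St, Se = Se)

  core <- ed$core
  if (!is.null(core)) {
    S <- core$S; Ts <- core$Ts; mA <- length(core$ids)
    StS <- St[S, S, drop = FALSE]
    SeS <- Se[S, S, drop = FALSE]
    E <- chol(SeS)
    Einv <- backsolve(E, diag(Ts))
    K <- crossprod(Einv, StS) %*% Einv
    eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
    Phi <- Einv %*% eg$vectors
    tPhi <- t(Phi)
    lam <- eg$values
    Dm <- 1 + outer(core$d, lam)
    if (any(Dm <= 0)) return(list(loglik = -Inf, bad = TRUE))
    logdetV <- logdetV + mA * 2 * sum(log(diag(E))) + sum(log(Dm))
    sDm <- sqrt(Dm)
    B2 <- xt <- vector("list", p1)
    FLAT <- matrix(0, mA * Ts, p1)
    for (c in seq_len(p1)) {
      B2c <- core$Zt[[c]] %*% Phi
      B2[[c]] <- B2c
      FLAT[, c] <- B2c / sDm
      xt[[c]] <- (B2c / Dm) %*% tPhi
    }
    CP <- CP + crossprod(FLAT)
    ev$Phi <- Phi; ev$lam <- lam; ev$Dm <- Dm; ev$xt <- xt
  }

  ex <- ed$extras
  if (!is.null(ex)) {
    b <- ex$b
    Vbb <- St[ex$t, ex$t, drop = FALSE] * ex$Gee_rec +
      Se[ex$t, ex$t, drop = FALSE] * ex$same_unit
    uB <- ex$ZB
    if (!is.null(core)) {
      S <- core$S
      at <- crossprod(ev$Phi, St[S, , drop = FALSE]) # Ts x T
      invDm <- 1 / ev$Dm
      CS <- vector("list", T)
      for (t in ex$ut) {
        CS[[t]] <- sweep(invDm, 2, at[, t], "*") %*% t(ev$Phi)
      }
      Corr <- matrix(0, b, b)
      for (t in ex$ut) {
        It <- which(ex$t == t)
        for (t2 in ex$ut) {
          It2 <- which(ex$t == t2)
          kv <- drop(invDm %*% (at[, t] * at[, t2]))
          Corr[It, It2] <- crossprod(ex$Hg[, It, drop = FALSE],
                                     ex$Hg[, It2, drop = FALSE] * kv)
        }
      }
      Q <- Vbb - Corr
      # u_B = z_B - V_BA A^{-1} z_A, via the separable cross-covariance
      StST <- St[S, , drop = FALSE]
      for (c in seq_len(p1)) {
        TT <- ev$xt[[c]] %*% StST  # mA x T
        uB[, c] <- uB[, c] - colSums(ex$Hg * TT[, ex$t, drop = FALSE])
      }
      ev$CS <- CS; ev$at <- at; ev$invDm <- invDm
    } else {
      Q <- Vbb
    }
    cholQ <- tryCatch(chol(Q), error = function(e) NULL)
    if (is.null(cholQ)) return(list(loglik = -Inf, bad = TRUE))
    logdetV <- logdetV + 2 * sum(log(diag(cholQ)))
    xB <- backsolve(cholQ, forwardsolve(t(cholQ), uB))
    CP <- CP + crossprod(uB, xB)
    ev$Q <- Q; ev$cholQ <- cholQ; ev$xB <- xB; ev$uB <- uB
    # correct rotated core solutions to the full V^{-1}z: x_A -= W~ x_B
    if (!is.null(core)) {
      for (c in seq_len(p1)) {
        for (t in ex$ut) {
          It <- which(ex$t == t)
          hw <- drop(ex$Hg[, It, drop = FALSE] %*% xB[It, c])
          ev$xt[[c]] <- ev$xt[[c]] - hw * ev$CS[[t]]
        }
      }
    }
  }

  nch <- length(ed$checks)
  ev$check_x <- vector("list", nch)
  ev$check_Einv <- vector("list", nch)
  for (ci in seq_len(nch)) {
    ch <- ed$checks[[ci]]
    Ec <- chol(Se[ch$S, ch$S, drop = FALSE])
    logdetV <- logdetV + ch$nu * 2 * sum(log(diag(Ec)))
    Einv <- chol2inv(Ec)
    xg <- lapply(ch$Zc, function(M) M %*% Einv)
    for (c in seq_len(p1)) {
      zc <- ch$Zc[[c]]
      for (c2 in c:p1) {
        v <- sum(zc * xg[[c2]])
        CP[c, c2] <- CP[c, c2] + v
        if (c2 != c) CP[c2, c] <- CP[c2, c] + v
      }
    }
    ev$check_x[[ci]] <- xg
    ev$check_Einv[[ci]] <- Einv
  }

  XtVX <- CP[seq_len(p), seq_len(p), drop = FALSE]
  XtVy <- CP[seq_len(p), p1]
  ytVy <- CP[p1, p1]
  cx <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(cx)) {
    stopf("fixed-effect design is singular given the data (X'V^-1X not positive definite)")
  }
  beta <- backsolve(cx, forwardsolve(t(cx), XtVy))
  logdet_XtVX <- 2 * sum(log(diag(cx)))
  rPy <- ytVy - sum(XtVy * beta)
  loglik <- -0.5 * (logdetV + logdet_XtVX + rPy + (ed$N - p) * log(2 * pi))

  ev$CP <- CP; ev$beta <- beta; ev$cholXtVX <- cx
  ev$logdetV <- logdetV; ev$loglik <- loglik
  ev
}

# Py in engine coordinates (rotated core, extras records, check units) plus
# the genotype x time aggregation Pmat used for BLUPs and gradients.
engine_py <- function(ev, ed) {
  w <- c(-ev$beta, 1)
  out <- list()
  if (!is.null(ed$core)) {
    Pt <- w[1] * ev$xt[[1]]
    for (c in seq_len(ed$p1)[-1]) Pt <- Pt + w[c] * ev$xt[[c]]
    out$Pt <- Pt
  }
  if (!is.null(ed$extras)) {
    out$PyB <- drop(ev$xB %*% w)
  }
  out$Pych <- lapply(seq_along(ed$checks), function(i) {
    xg <- ev$check_x[[i]]
    m <- w[1] * xg[[1]]
    for (c in seq_len(ed$p1)[-1]) m <- m + w[c] * xg[[c]]
    m
  })
  m_rand <- length(ed$rand_ids)
  Pmat <- matrix(0, m_rand, ed$T)
  if (!is.null(ed$core)) {
    Pmat[seq_along(ed$core$ids), ed$core$S] <- ed$core$U %*% out$Pt
  }
  if (!is.null(ed$extras)) {
    off <- length(ed$core$ids %||% character(0))
    for (r in seq_len(ed$extras$b)) {
      gi <- off + ed$extras$g[r]
      Pmat[gi, ed$extras$t[r]] <- Pmat[gi, ed$extras$t[r]] + out$PyB[r]
    }
  }
  out$Pmat <- Pmat
  out
}

# ---------------------------------------------------------------------------
# analytic gradient: full-matrix derivatives dl/dSigma_t, dl/dSigma_e

engine_gradient_matrices <- function(ev, ed) {
  T <- ed$T; p <- ed$p; p1 <- ed$p1
  XtVXi <- chol2inv(ev$cholXtVX)
  py <- engine_py(ev, ed)
  core <- ed$core; ex <- ed$extras
  w <- c(-ev$beta, 1)

  # stacked, T-padded rotated solutions (core) and extras aggregations
  if (!is.null(core)) {
    mA <- length(core$ids); S <- core$S; Ts <- core$Ts
    FM <- matrix(0, mA, T * p1)
    for (c in seq_len(p1)) FM[, (c - 1L) * T + S] <- ev$xt[[c]]
  }
  if (!is.null(ex)) {
    bG <- length(ex$ids)
    XeF <- matrix(0, bG, T * p1)
    for (c in seq_len(p1)) {
      for (r in seq_len(ex$b)) {
        j <- (c - 1L) * T + ex$t[r]
        XeF[ex$g[r], j] <- XeF[ex$g[r], j] + ev$xB[r, c]
      }
    }
  }

  # Theta[(a,c),(b,c2)] = (V^-1 z_c)' (G (x) e_a e_b') (V^-1 z_c2) summed
  # over random genotypes
  Theta <- matrix(0, T * p1, T * p1)
  if (!is.null(core)) Theta <- Theta + crossprod(FM * sqrt(core$d))
  if (!is.null(ex)) {
    if (!is.null(core)) {
      CE <- crossprod(FM, ex$Hge %*% XeF)
      Theta <- Theta + CE + t(CE)
    }
    Theta <- Theta + crossprod(XeF, ex$Gee %*% XeF)
  }
  Wk <- kronecker(w, diag(T))
  quadG <- crossprod(Wk, Theta %*% Wk)
  trX <- contract_blocks(Theta, XtVXi, T, p1)

  # G-contraction of V^{-1}
  trV <- matrix(0, T, T)
  if (!is.null(core)) {
    wts <- colSums(core$d / ev$Dm)
    trV <- trV + pad_T(ev$Phi %*% (wts * t(ev$Phi)), S, T)
  }
  if (!is.null(ex)) {
    Qinv <- chol2inv(ev$cholQ)
    if (!is.null(core)) {
      for (t in ex$ut) {
        It <- which(ex$t == t)
        nIt <- length(It)
        P1d <- P10 <- matrix(0, mA, Ts * nIt)
        for (ai in seq_len(Ts)) {
          cols <- (ai - 1L) * nIt + seq_len(nIt)
          HgIt <- ex$Hg[, It, drop = FALSE]
          P1d[, cols] <- HgIt * (core$d * ev$CS[[t]][, ai])
          P10[, cols] <- HgIt * ev$CS[[t]][, ai]
        }
        for (t2 in ex$ut) {
          It2 <- which(ex$t == t2)
          nIt2 <- length(It2)
          P2 <- matrix(0, mA, Ts * nIt2)
          for (bi in seq_len(Ts)) {
            cols <- (bi - 1L) * nIt2 + seq_len(nIt2)
            P2[, cols] <- ex$Hg[, It2, drop = FALSE] * ev$CS[[t2]][, bi]
          }
          CR <- crossprod(P1d, P2)
          Qblk <- Qinv[It, It2, drop = FALSE]
          for (ai in seq_len(Ts)) {
            ra <- (ai - 1L) * nIt + seq_len(nIt)
            for (bi in seq_len(Ts)) {
              cb <- (bi - 1L) * nIt2 + seq_len(nIt2)
              trV[S[ai], S[bi]] <- trV[S[ai], S[bi]] +
                sum(Qblk * CR[ra, cb, drop = FALSE])
            }
          }
        }
        # core-extras cross blocks of V^{-1} (= -W~ Q^{-1}), contracted
        # with G_ce; J_ab couples a core record at a with an extras record
        # at b, plus the transposed pairing
        CR0 <- crossprod(P10, ex$Hg)
        TAB <- matrix(0, T, T)
        for (ai in seq_len(Ts)) {
          ra <- (ai - 1L) * nIt + seq_len(nIt)
          for (t2 in ex$ut) {
            It2 <- which(ex$t == t2)
            TAB[S[ai], t2] <- TAB[S[ai], t2] -
              sum(Qinv[It, It2, drop = FALSE] * CR0[ra, It2, drop = FALSE])
          }
        }
        trV <- trV + TAB + t(TAB)
      }
    }
    GQ <- ex$Gee_rec * Qinv
    for (t in ex$ut) {
      It <- which(ex$t == t)
      for (t2 in ex$ut) {
        trV[t, t2] <- trV[t, t2] + sum(GQ[It, ex$t == t2])
      }
    }
  }
  Gt <- -0.5 * (trV - trX - quadG)

  # ---- residual part -----------------------------------------------------
  quadE <- matrix(0, T, T)
  trVe <- matrix(0, T, T)
  trXe <- matrix(0, T, T)
  if (!is.null(core)) {
    quadE <- quadE + pad_T(crossprod(py$Pt), S, T)
    wts1 <- colSums(1 / ev$Dm)
    trVe <- trVe + pad_T(ev$Phi %*% (wts1 * t(ev$Phi)), S, T)
    trXe <- trXe + contract_blocks(crossprod(FM), XtVXi, T, p1)
    if (!is.null(ex)) {
      Qinv <- chol2inv(ev$cholQ)
      for (t in ex$ut) {
        It <- which(ex$t == t)
        nIt <- length(It)
        P10 <- matrix(0, mA, Ts * nIt)
        for (ai in seq_len(Ts)) {
          cols <- (ai - 1L) * nIt + seq_len(nIt)
          P10[, cols] <- ex$Hg[, It, drop = FALSE] * ev$CS[[t]][, ai]
        }
        for (t2 in ex$ut) {
          It2 <- which(ex$t == t2)
          nIt2 <- length(It2)
          P2 <- matrix(0, mA, Ts * nIt2)
          for (bi in seq_len(Ts)) {
            cols <- (bi - 1L) * nIt2 + seq_len(nIt2)
            P2[, cols] <- ex$Hg[, It2, drop = FALSE] * ev$CS[[t2]][, bi]
          }
          CR <- crossprod(P10, P2)
          Qblk <- Qinv[It, It2, drop = FALSE]
          for (ai in seq_len(Ts)) {
            ra <- (ai - 1L) * nIt + seq_len(nIt)
            for (bi in seq_len(Ts)) {
              cb <- (bi - 1L) * nIt2 + seq_len(nIt2)
              trVe[S[ai], S[bi]] <- trVe[S[ai], S[bi]] +
                sum(Qblk * CR[ra, cb, drop = FALSE])
            }
          }
        }
      }
    }
  }
  if (!is.null(ex)) {
    Qinv <- chol2inv(ev$cholQ)
    su <- ex$same_unit
    xBX <- ev$xB[, seq_len(p), drop = FALSE]
    xBW <- xBX %*% XtVXi
    for (r in seq_len(ex$b)) {
      for (r2 in which(su[r, ])) {
        a <- ex$t[r]; bb <- ex$t[r2]
        quadE[a, bb] <- quadE[a, bb] + py$PyB[r] * py$PyB[r2]
        trVe[a, bb] <- trVe[a, bb] + Qinv[r, r2]
        trXe[a, bb] <- trXe[a, bb] + sum(xBW[r, ] * xBX[r2, ])
      }
    }
  }
  for (ci in seq_along(ed$checks)) {
    ch <- ed$checks[[ci]]
    Sc <- ch$S
    quadE[Sc, Sc] <- quadE[Sc, Sc] + crossprod(py$Pych[[ci]])
    trVe[Sc, Sc] <- trVe[Sc, Sc] + ch$nu * ev$check_Einv[[ci]]
    xg <- ev$check_x[[ci]]
    nsc <- length(Sc)
    CC <- matrix(0, nsc, nsc)
    for (a in seq_len(nsc)) {
      Wa <- matrix(0, ch$nu, p)
      for (c in seq_len(p)) Wa[, c] <- xg[[c]][, a]
      WaX <- Wa %*% XtVXi
      for (bb in seq_len(nsc)) {
        Wb <- matrix(0, ch$nu, p)
        for (c in seq_len(p)) Wb[, c] <- xg[[c]][, bb]
        CC[a, bb] <- sum(WaX * Wb)
      }
    }
    trXe[Sc, Sc] <- trXe[Sc, Sc] + CC
  }
  Ge <- -0.5 * (trVe - trXe - quadE)

  list(Gt = Gt, Ge = Ge, py = py)
}

# ---------------------------------------------------------------------------
# top-level REML driver

engine_reml <- function(ed, gen_struct, res_struct,
                        init_sigma_t, init_sigma_e,
                        tol = 1e-8, max_iter = 200L) {
  T <- ed$T
  th_t <- sigma_to_theta(init_sigma_t, gen_struct, T)
  th_e <- sigma_to_theta(init_sigma_e, res_struct, T)
  nt <- length(th_t)
  theta0 <- c(th_t, th_e)
  bt <- theta_bounds(gen_struct, T)
  be <- theta_bounds(res_struct, T)

  split_sigmas <- function(theta) {
    list(St = theta_to_sigma(theta[seq_len(nt)], gen_struct, T),
         Se = theta_to_sigma(theta[-seq_len(nt)], res_struct, T))
  }
  cache <- new.env(parent = emptyenv())
  get_ev <- function(theta) {
    if (!is.null(cache$theta) && identical(cache$theta, theta)) return(cache$ev)
    sg <- split_sigmas(theta)
    ev <- engine_eval(sg$St, sg$Se, ed)
    cache$theta <- theta
    cache$ev <- ev
    ev
  }
  fn <- function(theta) {
    ev <- get_ev(theta)
    if (!is.null(ev$bad)) return(1e12)
    -ev$loglik
  }
  gr <- function(theta) {
    ev <- get_ev(theta)
    if (!is.null(ev$bad)) return(rep(0, length(theta)))
    gm <- engine_gradient_matrices(ev, ed)
    -c(sigma_grad_chain(gm$Gt, theta[seq_len(nt)], gen_struct, T),
       sigma_grad_chain(gm$Ge, theta[-seq_len(nt)], res_struct, T))
  }

  # Quasi-Newton with restarts: re-running L-BFGS-B from the incumbent with
  # a fresh Hessian approximation escapes premature flat-spot stops; iterate
  # until a restart no longer improves the restricted log-likelihood.
  run_once <- function(start) {
    stats::optim(start, fn = fn, gr = gr, method = "L-BFGS-B",
                 lower = c(bt$lower, be$lower),
                 upper = c(bt$upper, be$upper),
                 control = list(maxit = max_iter,
                                factr = tol / .Machine$double.eps))
  }
  opt <- run_once(theta0)
  evals <- unname(opt$counts[1])
  for (restart in 1:3) {
    opt2 <- run_once(opt$par)
    evals <- evals + unname(opt2$counts[1])
    gain <- opt$value - opt2$value
    if (opt2$value < opt$value) opt <- opt2
    if (gain < max(tol * abs(opt$value), 1e-9)) break
  }
  sg <- split_sigmas(opt$par)
  ev <- engine_eval(sg$St, sg$Se, ed)
  py <- engine_py(ev, ed)
  list(theta = opt$par, sigma_t = sg$St, sigma_e = sg$Se,
       loglik = ev$loglik, beta = ev$beta,
       vcov_beta = chol2inv(ev$cholXtVX),
       Pmat = py$Pmat,
       n_params = length(opt$par),
       converged = opt$convergence == 0,
       n_iter = evals,
       message = opt$message %||% "")
}
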