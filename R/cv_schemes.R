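#' Random k-fold partition of genotypes
#'
#' Near-equal random partition (sizes differ by at most one). Ids listed in
#' `always_train` (e.g. experimental checks, which are fixed effects and not
#' predictable random effects) are never assigned to a test fold: they get
#' fold 0 and stay in every training set.
#'
#' @param ids Character vector of genotype ids.
#' @param k Number of folds (default 10); must not exceed the number of
#'   assignable ids.
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @param always_train Ids to keep in training in every fold.
#' @return Named integer vector: fold number per id (0 = always training).
#' @export
make_folds <- function(ids, k = 10L, seed = 1L, always_train = character(0)) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stopf("fold ids must be unique")
  assignable <- setdiff(ids, always_train)
  n <- length(assignable)
  if (k > n) stopf("k = %d exceeds the %d assignable genotypes", k, n)
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(k), n))
  out <- stats::setNames(integer(length(ids)), ids)
  out[assignable] <- fold
  out
}

#' Prediction ability
#'
#' Pearson correlation between genomic estimated breeding values and
#' phenotypic values, the standard accuracy proxy of genomic prediction
#' studies.
#'
#' @param gebv,pheno Numeric vectors of equal length (>= 3).
#' @return Pearson correlation.
#' @export
prediction_ability <- function(gebv, pheno) {
  if (length(gebv) != length(pheno)) stopf("gebv and pheno lengths differ")
  ok <- !is.na(gebv) & !is.na(pheno)
  if (sum(ok) < 3) stopf("need >= 3 paired observations (found %d)", sum(ok))
  if (stats::var(gebv[ok]) == 0 || stats::var(pheno[ok]) == 0) {
    stopf("zero variance in gebv or pheno; correlation undefined")
  }
  stats::cor(gebv[ok], pheno[ok])
}

# Fixed-effect-adjusted phenotypes for a set of records, using the training
# fit's estimates: value minus the time mean, year effect and (for checks)
# check effect.
adjust_records <- function(fit, df, adjust) {
  if (adjust == "raw") return(df$value)
  b <- fit$beta
  tadj <- b[paste0("time_", as.character(df$time_point))]
  yadj <- rep(0, nrow(df))
  ynames <- paste0("year_", df$year)
  hit <- ynames %in% names(b)
  yadj[hit] <- b[ynames[hit]]
  cadj <- rep(0, nrow(df))
  cnames <- paste0("check_", df$genotype_id)
  hit <- df$is_check & cnames %in% names(b)
  cadj[hit] <- b[cnames[hit]]
  df$value - as.numeric(tadj) - yadj - cadj
}

cv_prepare <- function(pheno, grm, spec) {
  df <- as.data.frame(pheno)
  df <- df[df$trait == spec$trait &
             as.character(df$time_point) %in% spec$time_points, , drop = FALSE]
  df <- as.data.frame(average_reps(phenotype_table(df)))
  df <- df[!is.na(df$value), , drop = FALSE]
  eligible <- sort(unique(df$genotype_id[!df$is_check]))
  miss <- setdiff(eligible, rownames(grm))
  if (length(miss) > 0) {
    stopf("genotype(s) missing from the relationship matrix: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  }
  checks <- unique(df$genotype_id[df$is_check])
  list(df = df, eligible = eligible, checks = checks)
}

#' CV1 cross-validation: predict genotypes with no phenotypic records
#'
#' The CV1 scheme deletes all records of the test genotypes, refits the
#' longitudinal model on the remaining genotypes, predicts the test GEBVs
#' through the relationship matrix, and correlates them with the test
#' genotypes' (fixed-effect-adjusted) phenotypes at each time point.
#' Prediction ability is pooled across folds within a repeat and averaged
#' over repeats. Check genotypes always stay in training.
#'
#' @param pheno A [phenotype_table()].
#' @param grm A [vanraden_grm()] result.
#' @param spec A [model_spec()].
#' @param k Folds, default 10.
#' @param n_repeats Repeats with fresh random partitions, default 10.
#' @param seed Master seed; per-repeat fold seeds are derived from it
#'   deterministically.
#' @param adjust `"fixed"` (default: correlate against phenotypes minus the
#'   training fit's time/year effects) or `"raw"`.
#' @param tol,max_iter Passed to [fit_longitudinal()].
#' @param warm_start If `TRUE` (default), each fold's optimizer starts from
#'   the previous fold's converged covariance estimates. Only the starting
#'   value is shared: every fold's REML solution is determined by its own
#'   training records and the convergence tolerance.
#' @param audit If `TRUE`, also return per-fold bookkeeping (training record
#'   keys, test ids) so leakage can be verified.
#' @return Object of class `cv_result`: `scheme = "CV1"`, `pa_mean` (named by
#'   time point), `pa_per_repeat` (repeats x time points), `k`, `n_repeats`,
#'   `seed`, and `audit` when requested.
#' @export
run_cv1 <- function(pheno, grm, spec, k = 10L, n_repeats = 10L, seed = 1L,
                    adjust = c("fixed", "raw"), tol = 1e-8, max_iter = 200L,
                    warm_start = TRUE, audit = FALSE) {
  adjust <- match.arg(adjust)
  prep <- cv_prepare(pheno, grm, spec)
  df <- prep$df
  times <- spec$time_points
  seeds <- derive_seeds(seed, n_repeats)
  pa <- matrix(NA_real_, n_repeats, length(times),
               dimnames = list(NULL, times))
  init <- NULL
  audit_log <- if (audit) vector("list", n_repeats) else NULL
  for (r in seq_len(n_repeats)) {
    folds <- make_folds(prep$eligible, k, seeds[r])
    pooled <- list()
    fold_log <- if (audit) vector("list", k) else NULL
    for (f in seq_len(k)) {
      test_ids <- names(folds)[folds == f]
      train_df <- df[!(df$genotype_id %in% test_ids), , drop = FALSE]
      fit <- fit_longitudinal(phenotype_table(train_df), grm, spec,
                              tol = tol, max_iter = max_iter, init = init)
      if (warm_start) init <- fit$components
      gebv <- predict_gebv(fit, test_ids)
      test_df <- df[df$genotype_id %in% test_ids, , drop = FALSE]
      test_df$adj <- adjust_records(fit, test_df, adjust)
      test_df$gebv <- gebv[cbind(match(test_df$genotype_id, rownames(gebv)),
                                 match(as.character(test_df$time_point), times))]
      pooled[[f]] <- test_df
      if (audit) {
        fold_log[[f]] <- list(
          test_ids = test_ids,
          train_keys = paste(train_df$genotype_id, train_df$year,
                             train_df$time_point, sep = "|"))
      }
    }
    pooled <- do.call(rbind, pooled)
    for (tt in times) {
      sub <- pooled[as.character(pooled$time_point) == tt, , drop = FALSE]
      if (nrow(sub) < 3) {
        warnf("repeat %d: fewer than 3 test phenotypes at %s; PA skipped", r, tt)
      } else {
        pa[r, tt] <- prediction_ability(sub$gebv, sub$adj)
      }
    }
    if (audit) audit_log[[r]] <- fold_log
  }
  structure(list(scheme = "CV1", trait = spec$trait, target_time = times,
                 pa_mean = colMeans(pa, na.rm = TRUE), pa_per_repeat = pa,
                 k = as.integer(k), n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed), adjust = adjust,
                 audit = audit_log),
            class = "cv_result")
}

#' CV2 cross-validation: predict a later time point knowing an earlier one
#'
#' In the CV2 scheme the test genotypes keep their records at `known_time`
#' (and only at it) in the training data; all their other records are
#' deleted. The longitudinal model propagates the known early phenotype to
#' the target time through the genetic covariance between time points.
#' Prediction ability is computed at `target_time` exactly as in [run_cv1()],
#' with the same fold partitions for a given seed (so CV1/CV2 comparisons can
#' be paired).
#'
#' @inheritParams run_cv1
#' @param known_time Time point whose records the test genotypes keep;
#'   must be strictly earlier than `target_time`.
#' @param target_time Predicted time point.
#' @return Object of class `cv_result` with `scheme = "CV2"`, scalar
#'   `pa_mean` and `pa_per_repeat` of length `n_repeats`.
#' @export
run_cv2 <- function(pheno, grm, spec, known_time, target_time, k = 10L,
                    n_repeats = 10L, seed = 1L, adjust = c("fixed", "raw"),
                    tol = 1e-8, max_iter = 200L, warm_start = TRUE,
                    audit = FALSE) {
  adjust <- match.arg(adjust)
  known_time <- as.character(known_time)
  target_time <- as.character(target_time)
  if (!all(c(known_time, target_time) %in% spec$time_points)) {
    stopf("known_time and target_time must be fitted time points")
  }
  if (match(known_time, TIME_LEVELS) >= match(target_time, TIME_LEVELS)) {
    stopf("known_time (%s) must be strictly earlier than target_time (%s)",
          known_time, target_time)
  }
  prep <- cv_prepare(pheno, grm, spec)
  df <- prep$df
  times <- spec$time_points
  seeds <- derive_seeds(seed, n_repeats)
  pa <- rep(NA_real_, n_repeats)
  init <- NULL
  audit_log <- if (audit) vector("list", n_repeats) else NULL
  for (r in seq_len(n_repeats)) {
    folds <- make_folds(prep$eligible, k, seeds[r])
    pooled <- list()
    fold_log <- if (audit) vector("list", k) else NULL
    for (f in seq_len(k)) {
      test_ids <- names(folds)[folds == f]
      is_test <- df$genotype_id %in% test_ids
      keep <- !is_test | as.character(df$time_point) == known_time
      train_df <- df[keep, , drop = FALSE]
      fit <- fit_longitudinal(phenotype_table(train_df), grm, spec,
                              tol = tol, max_iter = max_iter, init = init)
      if (warm_start) init <- fit$components
      gebv <- predict_gebv(fit, test_ids)
      test_df <- df[is_test & as.character(df$time_point) == target_time, ,
                    drop = FALSE]
      test_df$adj <- adjust_records(fit, test_df, adjust)
      test_df$gebv <- gebv[match(test_df$genotype_id, rownames(gebv)),
                           match(target_time, times)]
      pooled[[f]] <- test_df
      if (audit) {
        fold_log[[f]] <- list(
          test_ids = test_ids,
          train_keys = paste(train_df$genotype_id, train_df$year,
                             train_df$time_point, sep = "|"))
      }
    }
    pooled <- do.call(rbind, pooled)
    if (nrow(pooled) < 3) {
      warnf("repeat %d: fewer than 3 test phenotypes at %s; PA skipped",
            r, target_time)
    } else {
      pa[r] <- prediction_ability(pooled$gebv, pooled$adj)
    }
    if (audit) audit_log[[r]] <- fold_log
  }
  structure(list(scheme = "CV2", trait = spec$trait,
                 known_time = known_time, target_time = target_time,
                 pa_mean = mean(pa, na.rm = TRUE), pa_per_repeat = pa,
                 k = as.integer(k), n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed), adjust = adjust,
                 audit = audit_log),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  if (x$scheme == "CV1") {
    cat(sprintf("cv_result: CV1, trait '%s', %d-fold x %d repeats (seed %d)\n",
                x$trait, x$k, x$n_repeats, x$seed))
    cat("  mean PA:",
        paste(sprintf("%s=%.3f", names(x$pa_mean), x$pa_mean), collapse = ", "),
        "\n")
  } else {
    cat(sprintf(
      "cv_result: CV2 (%s known -> %s), trait '%s', %d-fold x %d repeats (seed %d)\n",
      x$known_time, x$target_time, x$trait, x$k, x$n_repeats, x$seed))
    cat(sprintf("  mean PA at %s: %.3f\n", x$target_time, x$pa_mean))
  }
  invisible(x)
}
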