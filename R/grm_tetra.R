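#' Alternate-allele frequencies from a dosage matrix
#'
#' Frequency of marker `j` is the mean non-missing dosage divided by the
#' ploidy, i.e. the sample allele frequency under polysomic inheritance.
#'
#' @param dosages A [dosage_matrix()].
#' @return Named numeric vector of frequencies in `[0, 1]`, one per marker.
#' @export
allele_frequencies <- function(dosages) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  ploidy <- attr(dosages, "ploidy")
  n_obs <- colSums(!is.na(dosages))
  if (any(n_obs == 0)) {
    stopf("marker(s) with no observed dosages: %s",
          paste(colnames(dosages)[n_obs == 0], collapse = ", "))
  }
  colMeans(unclass(dosages), na.rm = TRUE) / ploidy
}

#' Tetrasomic VanRaden genomic relationship matrix
#'
#' Builds the additive genomic relationship matrix `G` from allele dosages
#' under polysomic inheritance, following the VanRaden construction
#' generalized to arbitrary even ploidy. With `M` the genotypes-by-markers
#' dosage matrix and `p_j` the allele frequency of marker `j`:
#' \deqn{W = M - \mathrm{ploidy}\,P, \qquad
#'       G = \frac{W W^\top}{\sum_j \mathrm{ploidy}\, p_j (1 - p_j)},}
#' where `P` has `p_j` in every row of column `j`. The denominator is the sum
#' of binomial dosage variances expected under polysomic Hardy-Weinberg
#' equilibrium, so the diagonal of `G` averages about 1 in an equilibrium
#' population. Setting `ploidy = 2` recovers the classical diploid VanRaden
#' matrix.
#'
#' Monomorphic markers and markers with minor allele frequency below
#' `min_maf` are excluded. Missing dosages are mean-imputed per marker after
#' the frequency computation (deterministic, standard practice). A small
#' `ridge` is added to the diagonal so `G` stays invertible inside mixed
#' models.
#'
#' @param dosages A [dosage_matrix()].
#' @param min_maf Minimum minor allele frequency; default 0 (no filter beyond
#'   removing monomorphic markers).
#' @param ridge Non-negative value added to the diagonal, default `1e-6`.
#' @return An object of class `genomic_relationship`: the symmetric `G` matrix
#'   with attributes `ploidy`, `n_markers_used` and `ridge`.
#' @examples
#' dm <- dosage_matrix(matrix(c(0L, 4L), 2, 1), c("a", "b"), "m1")
#' vanraden_grm(dm, ridge = 0) # [[4, -4], [-4, 4]]
#' @export
vanraden_grm <- function(dosages, min_maf = 0, ridge = 1e-6) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  if (nrow(dosages) < 2) stopf("at least 2 genotypes are required")
  if (ridge < 0) stopf("ridge must be non-negative")
  ploidy <- attr(dosages, "ploidy")
  p <- allele_frequencies(dosages)
  maf <- pmin(p, 1 - p)
  # a marker is polymorphic only if it actually varies across genotypes
  varies <- apply(unclass(dosages), 2, function(x) {
    x <- x[!is.na(x)]
    length(x) > 0 && any(x != x[1])
  })
  keep <- varies & maf > 0 & maf >= min_maf
  if (!any(keep)) stopf("no polymorphic markers pass the MAF filter (min_maf = %g)", min_maf)
  M <- unclass(dosages)[, keep, drop = FALSE]
  storage.mode(M) <- "double"
  p <- p[keep]
  # mean imputation of missing dosages, per marker
  if (anyNA(M)) {
    na_idx <- which(is.na(M), arr.ind = TRUE)
    M[na_idx] <- (ploidy * p)[na_idx[, 2]]
  }
  W <- sweep(M, 2, ploidy * p, "-")
  denom <- sum(ploidy * p * (1 - p))
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  diag(G) <- diag(G) + ridge
  dimnames(G) <- list(rownames(dosages), rownames(dosages))
  structure(G, ploidy = ploidy, n_markers_used = sum(keep), ridge = ridge,
            class = c("genomic_relationship", "matrix", "array"))
}

#' @export
print.genomic_relationship <- function(x, ...) {
  cat(sprintf("genomic_relationship: %d genotypes, %d markers used, ploidy %d, mean diag %.3f\n",
              nrow(x), attr(x, "n_markers_used"), attr(x, "ploidy"),
              mean(diag(x))))
  invisible(x)
}

# Subset a genomic_relationship to a set of genotype ids, keeping attributes.
grm_subset <- function(grm, ids) {
  miss <- setdiff(ids, rownames(grm))
  if (length(miss) > 0) {
    stopf("genotype id(s) absent from the relationship matrix: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  }
  G <- unclass(grm)[ids, ids, drop = FALSE]
  structure(G, ploidy = attr(grm, "ploidy"),
            n_markers_used = attr(grm, "n_markers_used"),
            ridge = attr(grm, "ridge"),
            class = c("genomic_relationship", "matrix", "array"))
}
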