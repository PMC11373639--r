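test_that("allele frequencies are mean dosage over ploidy", {
  dm <- dosage_matrix(matrix(c(0L, 2L, 4L, 4L, 4L, 4L), 3, 2),
                      c("a", "b", "c"), c("m1", "m2"))
  p <- allele_frequencies(dm)
  expect_equal(unname(p), c(0.5, 1))
  dm2 <- dosage_matrix(matrix(0:4, 5, 1), paste0("g", 1:5), "m1")
  expect_equal(unname(allele_frequencies(dm2)), 0.5)
})

test_that("markers with no observed dosages are rejected by name", {
  m <- matrix(c(1L, 2L, NA, NA), 2, 2)
  dm <- dosage_matrix(m, c("a", "b"), c("ok", "empty"))
  expect_error(allele_frequencies(dm), "empty")
})

test_that("the two-genotype one-marker toy matches hand arithmetic", {
  dm <- dosage_matrix(matrix(c(0L, 4L), 2, 1), c("a", "b"), "m1")
  G <- vanraden_grm(dm, ridge = 0)
  expect_equal(unname(unclass(G)[, ]), matrix(c(4, -4, -4, 4), 2), tolerance = 1e-12)
})

test_that("duplicated genotypes give identical relationship rows", {
  set.seed(7)
  m <- matrix(rbinom(5 * 50, 4, 0.4), 5, 50)
  m <- rbind(m, m[3, ])
  dm <- dosage_matrix(m, paste0("g", 1:6), paste0("m", 1:50))
  G <- vanraden_grm(dm, ridge = 0)
  expect_equal(unclass(G)["g3", ], unclass(G)["g6", ], tolerance = 1e-12)
  expect_equal(unclass(G)[, "g3"], unclass(G)[, "g6"], tolerance = 1e-12)
})

test_that("a fully monomorphic panel is rejected", {
  dm <- dosage_matrix(matrix(2L, 4, 10), paste0("g", 1:4), paste0("m", 1:10))
  expect_error(vanraden_grm(dm), "polymorphic")
})

test_that("G is invariant to marker order and equivariant to genotype order", {
  set.seed(8)
  m <- matrix(rbinom(6 * 80, 4, 0.3), 6, 80)
  dm <- dosage_matrix(m, paste0("g", 1:6), paste0("m", 1:80))
  G1 <- vanraden_grm(dm)
  perm <- sample(80)
  dm2 <- dosage_matrix(m[, perm], paste0("g", 1:6), paste0("m", 1:80)[perm])
  G2 <- vanraden_grm(dm2)
  expect_equal(unclass(G1)[, ], unclass(G2)[, ], tolerance = 1e-12)
  gperm <- c(3, 1, 2, 6, 5, 4)
  dm3 <- dosage_matrix(m[gperm, ], paste0("g", 1:6)[gperm], paste0("m", 1:80))
  G3 <- vanraden_grm(dm3)
  expect_equal(unclass(G3)[, ], unclass(G1)[gperm, gperm], tolerance = 1e-12)
})

test_that("diagonal averages ~1 under binomial equilibrium and G is PSD", {
  set.seed(9)
  p <- runif(1200, 0.1, 0.5)
  m <- matrix(rbinom(200 * 1200, 4, rep(p, each = 200)), 200, 1200)
  dm <- dosage_matrix(m, sprintf("g%03d", 1:200), sprintf("m%04d", 1:1200))
  G <- vanraden_grm(dm, ridge = 0)
  expect_lt(abs(mean(diag(G)) - 1), 0.1)
  ev <- eigen(unclass(G)[, ], symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("ploidy 2 reproduces the classical diploid VanRaden matrix", {
  set.seed(10)
  m <- matrix(rbinom(8 * 100, 2, 0.4), 8, 100)
  dm <- dosage_matrix(m, paste0("g", 1:8), paste0("m", 1:100), ploidy = 2L)
  G <- vanraden_grm(dm, ridge = 0)
  # direct diploid VanRaden computed independently
  p <- colMeans(m) / 2
  keep <- p > 0 & p < 1 & apply(m, 2, function(x) length(unique(x)) > 1)
  W <- sweep(m[, keep], 2, 2 * p[keep], "-")
  G_ref <- W %*% t(W) / (2 * sum(p[keep] * (1 - p[keep])))
  expect_equal(unname(unclass(G)[, ]), unname(G_ref), tolerance = 1e-10)
})

test_that("missing dosages are mean-imputed deterministically", {
  m <- matrix(c(0L, 2L, 4L, NA, 1L, 3L, 2L, 0L), 4, 2)
  dm <- dosage_matrix(m, paste0("g", 1:4), c("m1", "m2"))
  G1 <- vanraden_grm(dm)
  G2 <- vanraden_grm(dm)
  expect_identical(unclass(G1)[, ], unclass(G2)[, ])
  # imputing at the marker mean leaves that genotype's centered entry at 0
  expect_false(anyNA(unclass(G1)))
})

test_that("the MAF filter drops rare markers from the denominator", {
  m <- cbind(c(0L, 0L, 0L, 1L), c(0L, 2L, 4L, 2L))
  dm <- dosage_matrix(m, paste0("g", 1:4), c("rare", "common"))
  G <- vanraden_grm(dm, min_maf = 0.2)
  expect_equal(attr(G, "n_markers_used"), 1L)
})
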