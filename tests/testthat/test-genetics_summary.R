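mk_components <- function(st, se) {
  structure(list(sigma_t = st, sigma_e = se), class = "covariance_components")
}

test_that("heritability is the per-time variance ratio", {
  st <- diag(c(2, 0)); se <- diag(c(2, 1))
  dimnames(st) <- dimnames(se) <- list(c("1D", "7W"), c("1D", "7W"))
  h2 <- heritability(mk_components(st, se))
  expect_equal(h2$h2, c(0.5, 0))
  expect_equal(h2$time_point, c("1D", "7W"))
  st0 <- diag(c(0, 1)); se0 <- diag(c(0, 1))
  expect_error(heritability(mk_components(st0, se0)), "zero")
})

test_that("genetic correlations rescale the covariance to unit diagonal", {
  expect_equal(genetic_correlations(mk_components(diag(c(2, 3)), diag(2))),
               diag(2), ignore_attr = TRUE)
  st <- matrix(c(1, 0.9, 0.9, 1), 2)
  expect_equal(genetic_correlations(mk_components(st, diag(2)))[1, 2], 0.9)
  st0 <- matrix(c(1, 0, 0, 0), 2)
  gc <- genetic_correlations(mk_components(st0, diag(2)))
  expect_true(is.na(gc[1, 2]) && is.na(gc[2, 2]))
  expect_equal(gc[1, 1], 1)
})

test_that("phenotypic correlations behave as Pearson correlations", {
  set.seed(71)
  n <- 40
  ids <- paste0("g", 1:n)
  v <- rnorm(n)
  df <- rbind(
    data.frame(genotype_id = ids, year = 2021L, time_point = "1D", trait = "a",
               value = v, is_check = FALSE, rep = 1L),
    data.frame(genotype_id = ids, year = 2021L, time_point = "1D", trait = "b",
               value = -v, is_check = FALSE, rep = 1L))
  pt <- phenotype_table(df)
  expect_equal(phenotypic_correlation(pt, "a", "a", "1D", "1D"), 1)
  expect_equal(phenotypic_correlation(pt, "a", "b", "1D", "1D"), -1)
  expect_error(phenotypic_correlation(pt[1:4, ], "a", "b", "1D", "1D"), ">= 3")
})

test_that("baseline R-squared is the squared phenotypic correlation", {
  set.seed(72)
  n <- 50
  ids <- paste0("g", 1:n)
  base <- rnorm(n)
  target <- 2 * base + 5
  noisy <- 0.8 * base + rnorm(n)
  df <- rbind(
    data.frame(genotype_id = ids, year = 2021L, time_point = "1D", trait = "f",
               value = base, is_check = FALSE, rep = 1L),
    data.frame(genotype_id = ids, year = 2021L, time_point = "1W", trait = "f",
               value = target, is_check = FALSE, rep = 1L),
    data.frame(genotype_id = ids, year = 2021L, time_point = "7W", trait = "f",
               value = noisy, is_check = FALSE, rep = 1L))
  pt <- phenotype_table(df)
  expect_equal(suppressWarnings(baseline_regression_r2(pt, "f", "1D", "1W")),
               1, tolerance = 1e-12)
  r2 <- baseline_regression_r2(pt, "f", "1D", "7W")
  r <- phenotypic_correlation(pt, "f", "f", "1D", "7W")
  expect_equal(r2, r^2, tolerance = 1e-10)
})

test_that("independent values explain almost nothing", {
  set.seed(73)
  n <- 1000
  ids <- paste0("g", 1:n)
  df <- rbind(
    data.frame(genotype_id = ids, year = 2021L, time_point = "1D", trait = "f",
               value = rnorm(n), is_check = FALSE, rep = 1L),
    data.frame(genotype_id = ids, year = 2021L, time_point = "7W", trait = "f",
               value = rnorm(n), is_check = FALSE, rep = 1L))
  pt <- phenotype_table(df)
  expect_lt(baseline_regression_r2(pt, "f", "1D", "7W"), 0.01)
  # constant baseline is rejected
  df$value[df$time_point == "1D"] <- 3
  expect_error(baseline_regression_r2(phenotype_table(df), "f", "1D", "7W"),
               "constant")
})

test_that("postharvest descriptives summarize changes against baseline", {
  ids <- paste0("g", 1:4)
  df <- rbind(
    data.frame(genotype_id = ids, year = 2021L, time_point = "1D", trait = "f",
               value = c(10, 10, 10, 10), is_check = FALSE, rep = 1L),
    data.frame(genotype_id = ids, year = 2021L, time_point = "7W", trait = "f",
               value = c(11, 12, 9, 8), is_check = FALSE, rep = 1L))
  d <- postharvest_descriptives(phenotype_table(df), "f")
  vb <- d$vs_baseline
  expect_equal(vb$mean_diff, 0)
  expect_equal(vb$prop_decreased, 0.5)
  expect_equal(vb$prop_increased, 0.5)
  expect_equal(vb$prop_decreased + vb$prop_increased + vb$prop_unchanged, 1)
  expect_equal(vb$prop_beyond_threshold, 1) # threshold 0, all strictly changed
  d2 <- postharvest_descriptives(phenotype_table(df), "f", threshold = 1.5)
  expect_equal(d2$vs_baseline$prop_beyond_threshold, 0.5)
})

test_that("a constant trait shows zero change everywhere", {
  df <- as.data.frame(toy_pheno())
  df$value <- 5
  d <- postharvest_descriptives(phenotype_table(df), "firmness")
  expect_true(all(d$vs_baseline$mean_diff == 0))
  expect_true(all(d$vs_baseline$prop_decreased == 0))
  expect_true(all(d$vs_baseline$prop_increased == 0))
  expect_true(all(d$vs_baseline$prop_unchanged == 1))
})

test_that("the genetic parameter table assembles h2, LRT and psi", {
  sim <- quick_sim(seed = 74, n_genotypes = 60, n_checks = 4,
                   time_points = c("1D", "7W"))
  gp <- genetic_parameter_table(sim$pheno, sim$grm,
                                model_spec("firmness", c("1D", "7W")),
                                psi_iter = 2000, seed = 3)
  expect_equal(gp$table$trait, "firmness")
  expect_true(all(c("h2_1D", "h2_7W", "lrt_p", "psi") %in% names(gp$table)))
  expect_true(gp$table$psi >= 0 && gp$table$psi <= 1)
})
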