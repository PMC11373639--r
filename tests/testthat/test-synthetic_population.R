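test_that("simulated dosages are valid tetraploid calls and seeded", {
  cfg <- simulation_config(n_genotypes = 50, n_markers = 100, n_qtl = 40, seed = 3)
  d1 <- simulate_dosages(cfg)
  expect_true(all(unclass(d1) %in% 0:4))
  d2 <- simulate_dosages(cfg)
  expect_identical(unclass(d1)[, ], unclass(d2)[, ])
  d3 <- simulate_dosages(simulation_config(n_genotypes = 50, n_markers = 100,
                                           n_qtl = 40, seed = 4))
  expect_false(identical(unclass(d1)[, ], unclass(d3)[, ]))
})

test_that("column frequencies track the generating allele frequencies", {
  cfg <- simulation_config(n_genotypes = 1000, n_markers = 60, n_qtl = 30, seed = 5)
  dos <- simulate_dosages(cfg)
  p <- attr(dos, "allele_freq")
  phat <- colMeans(unclass(dos)) / 4
  se <- sqrt(p * (1 - p) / (4 * 1000))
  expect_true(all(abs(phat - p) <= 3.5 * se))
})

test_that("the noiseless limit returns the breeding values", {
  cfg <- simulation_config(n_genotypes = 40, n_checks = 2, n_years = 1,
                           n_markers = 80, n_qtl = 40,
                           h2_target = 1 - 1e-8, residual_var = 1e-8,
                           n_reps = 1, seed = 6, time_points = c("1D", "1W"))
  dos <- simulate_dosages(cfg)
  sim <- simulate_phenotypes(dos, cfg)
  df <- as.data.frame(sim$pheno)
  u <- sim$truth$breeding_values
  tm <- sim$truth$time_means
  for (i in seq_len(nrow(df))) {
    expected <- tm[as.character(df$time_point[i])] +
      u[df$genotype_id[i], as.character(df$time_point[i])]
    expect_equal(df$value[i], unname(expected), tolerance = 1e-2)
  }
})

test_that("realized heritability lands near its target at study scale", {
  cfg <- simulation_config(seed = 1)
  dos <- simulate_dosages(cfg)
  sim <- simulate_phenotypes(dos, cfg)
  expect_true(all(abs(sim$truth$realized_h2 - 0.5) <= 0.05))
})

test_that("true breeding values reproduce the analytic crossover proportion", {
  cfg <- simulation_config(n_genotypes = 2000, n_checks = 2, n_markers = 300,
                           n_qtl = 300, time_points = c("1D", "7W"),
                           genetic_corr_lag = 0.5, seed = 7)
  dos <- simulate_dosages(cfg)
  sim <- simulate_phenotypes(dos, cfg)
  psi <- psi_exact(sim$truth$breeding_values, "1D", "7W")$psi
  rho <- sim$truth$realized_genetic_corr[1, 2]
  expect_lt(abs(psi - acos(rho) / pi), 0.02)
})

test_that("checks appear in every year and others in exactly one", {
  sim <- quick_sim(seed = 8, n_genotypes = 30, n_checks = 3, n_years = 3,
                   n_markers = 50, n_qtl = 20)
  df <- as.data.frame(sim$pheno)
  yrs <- tapply(df$year, df$genotype_id, function(x) length(unique(x)))
  chk <- unique(df$genotype_id[df$is_check])
  expect_true(all(yrs[chk] == 3))
  expect_true(all(yrs[setdiff(names(yrs), chk)] == 1))
})

test_that("the missingness injector restricts a trait to chosen times", {
  sim <- quick_sim(seed = 9, n_genotypes = 20, n_checks = 2,
                   n_markers = 40, n_qtl = 10)
  out <- restrict_trait_times(sim$pheno, "firmness", "7W")
  expect_equal(unique(as.character(out$time_point)), "7W")
})

test_that("generated data round-trip through the text formats unchanged", {
  sim <- quick_sim(seed = 10, n_genotypes = 15, n_checks = 2,
                   n_markers = 30, n_qtl = 10)
  fg <- withr::local_tempfile(fileext = ".csv")
  fp <- withr::local_tempfile(fileext = ".csv")
  write_dosage_matrix(sim$dosages, fg)
  write_phenotypes(sim$pheno, fp)
  expect_identical(unclass(read_dosage_matrix(fg))[, ], unclass(sim$dosages)[, ])
  expect_equal(as.data.frame(read_phenotypes(fp)), as.data.frame(sim$pheno),
               tolerance = 1e-12)
})

test_that("infeasible targets are rejected", {
  expect_error(simulation_config(h2_target = 1), "strictly")
  expect_error(simulation_config(h2_target = 0), "strictly")
  expect_error(simulation_config(n_checks = 600), "smaller")
})
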