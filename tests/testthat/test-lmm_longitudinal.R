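test_that("pure-noise data yields near-zero genetic variance", {
  # Under the null the REML genetic variance piles up at the zero boundary
  # with a half-normal tail of the order of its standard error, so single
  # fits scatter; the average over replicates must be close to zero and no
  # single estimate should approach the residual variance.
  ratios <- c()
  for (s in 55:59) {
    set.seed(s)
    n <- 200L
    ids <- sprintf("g%03d", seq_len(n))
    dos <- dosage_matrix(matrix(rbinom(n * 150, 4, 0.35), n, 150), ids,
                         sprintf("m%03d", 1:150))
    G <- vanraden_grm(dos)
    tp <- c("1D", "1W")
    ph <- phenotype_table(data.frame(
      genotype_id = rep(ids, each = 2), year = 2021L,
      time_point = rep(tp, n), trait = "noise",
      value = rnorm(2 * n), is_check = FALSE, rep = 1L))
    fit <- fit_longitudinal(ph, G, model_spec("noise", tp))
    ratios <- c(ratios,
                diag(fit$components$sigma_t) / diag(fit$components$sigma_e))
  }
  expect_lt(mean(ratios), 0.05)
  expect_lt(max(ratios), 0.25)
})

test_that("unphenotyped genotypes follow the conditional-expectation closed form", {
  inst <- tiny_two_time_instance(21)
  ids <- inst$ids
  # leave the last two genotypes unphenotyped
  obs <- ids[seq_len(length(ids) - 2)]
  new <- setdiff(ids, obs)
  ph <- phenotype_table(as.data.frame(inst$pheno)[inst$pheno$genotype_id %in% obs, ])
  fit <- fit_longitudinal(ph, inst$grm, model_spec("x", c("1D", "1W")))
  u_obs <- fit$blups[obs, , drop = FALSE]
  Gm <- unclass(inst$grm)
  u_new_ref <- Gm[new, obs] %*% solve(Gm[obs, obs]) %*% u_obs
  expect_equal(predict_gebv(fit, new), u_new_ref, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("a genotype duplicating a training genotype's relationships shares its GEBV", {
  set.seed(33)
  n <- 10
  m <- matrix(rbinom(n * 80, 4, 0.4), n, 80)
  m <- rbind(m, m[2, ]) # twin of g2, unphenotyped
  ids <- c(paste0("g", 1:n), "twin")
  dos <- dosage_matrix(m, ids, paste0("mk", 1:80))
  G <- vanraden_grm(dos)
  ph <- phenotype_table(data.frame(
    genotype_id = rep(paste0("g", 1:n), each = 2), year = 2021L,
    time_point = rep(c("1D", "1W"), n), trait = "x",
    value = rnorm(2 * n), is_check = FALSE, rep = 1L))
  fit <- fit_longitudinal(ph, G, model_spec("x", c("1D", "1W")))
  expect_equal(predict_gebv(fit, "twin")[1, ], fit$blups["g2", ],
               tolerance = 1e-5)
})

test_that("genotypes unrelated to all training genotypes predict to zero", {
  inst <- tiny_two_time_instance(22)
  Gm <- unclass(inst$grm)
  ids2 <- c(inst$ids, "stranger")
  G2 <- rbind(cbind(Gm, 0), 0)
  dimnames(G2) <- list(ids2, ids2)
  G2["stranger", "stranger"] <- 1
  G2 <- structure(G2, class = c("genomic_relationship", "matrix", "array"))
  fit <- fit_longitudinal(inst$pheno, G2, model_spec("x", c("1D", "1W")))
  expect_equal(unname(predict_gebv(fit, "stranger")[1, ]), c(0, 0),
               tolerance = 1e-10)
  expect_error(predict_gebv(fit, "nobody"), "unknown")
})

test_that("BIC applies its defining formula", {
  fake <- structure(list(loglik = -100, n_params = 3L, n_records = 100L,
                         converged = TRUE),
                    class = "longitudinal_fit")
  expect_equal(bic(fake), 200 + 3 * log(100))
  fake$converged <- FALSE
  expect_warning(bic(fake), "non-converged")
})

test_that("the Wald time test detects injected time effects and needs >= 2 times", {
  sim <- quick_sim(seed = 61, n_genotypes = 60, n_checks = 4,
                   time_points = c("1D", "1W"), time_effect_step = 3)
  fit <- fit_longitudinal(sim$pheno, sim$grm,
                          model_spec("firmness", c("1D", "1W")))
  wt <- wald_time_effect(fit)
  expect_lt(wt$p_value, 1e-6)
  expect_equal(wt$df, 1L)

  ph1 <- phenotype_table(as.data.frame(sim$pheno)[sim$pheno$time_point == "1D", ])
  fit1 <- fit_longitudinal(ph1, sim$grm, model_spec("firmness", "1D"))
  expect_error(wald_time_effect(fit1), "two time points")
})

test_that("the Wald statistic is invariant to genotype relabeling", {
  sim <- quick_sim(seed = 62, n_genotypes = 40, n_checks = 3,
                   n_markers = 80, n_qtl = 30, time_points = c("1D", "1W"))
  fit <- fit_longitudinal(sim$pheno, sim$grm,
                          model_spec("firmness", c("1D", "1W")))
  df <- as.data.frame(sim$pheno)
  ids <- unique(df$genotype_id)
  relab <- stats::setNames(paste0("z", seq_along(ids)), ids)
  df$genotype_id <- unname(relab[df$genotype_id])
  Gm <- unclass(sim$grm)
  dimnames(Gm) <- list(unname(relab[rownames(Gm)]), unname(relab[colnames(Gm)]))
  Gm <- structure(Gm, class = c("genomic_relationship", "matrix", "array"))
  fit2 <- fit_longitudinal(phenotype_table(df), Gm,
                           model_spec("firmness", c("1D", "1W")))
  expect_equal(wald_time_effect(fit2)$statistic, wald_time_effect(fit)$statistic,
               tolerance = 1e-6)
})

test_that("the interaction LRT is zero for identical fits and validates nesting", {
  sim <- quick_sim(seed = 63, n_genotypes = 50, n_checks = 3,
                   time_points = c("1D", "1W"))
  spec_f <- model_spec("firmness", c("1D", "1W"), genetic = "us")
  spec_r <- model_spec("firmness", c("1D", "1W"), genetic = "common")
  full <- fit_longitudinal(sim$pheno, sim$grm, spec_f)
  red <- fit_longitudinal(sim$pheno, sim$grm, spec_r)
  lrt <- lrt_interaction(full, red)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 2L)
  expect_true(lrt$p_value >= 0 && lrt$p_value <= 1)
  # degenerate: the reduced slot must really be the no-interaction model
  expect_error(lrt_interaction(full, full), "common")
  # two fits with equal likelihood -> statistic 0, p-value 1
  pseudo_full <- red
  pseudo_full$spec$genetic <- "us"
  pseudo_full$n_params <- red$n_params + 2L
  lrt0 <- lrt_interaction(pseudo_full, red)
  expect_equal(lrt0$statistic, 0)
  expect_equal(lrt0$p_value, 1)
})

test_that("missing records at some time points are handled record-wise", {
  sim <- quick_sim(seed = 64, n_genotypes = 50, n_checks = 3)
  df <- as.data.frame(sim$pheno)
  # drop 7W for a third of the genotypes
  ids <- unique(df$genotype_id[!df$is_check])
  dropg <- ids[seq_len(15)]
  df <- df[!(df$genotype_id %in% dropg & df$time_point == "7W"), ]
  fit <- fit_longitudinal(phenotype_table(df), sim$grm, model_spec("firmness"))
  expect_true(fit$converged)
  expect_equal(nrow(fit$blups), nrow(sim$grm))
})

test_that("phenotyped genotypes missing from G are reported", {
  sim <- quick_sim(seed = 65, n_genotypes = 30, n_checks = 2,
                   n_markers = 60, n_qtl = 20)
  Gm <- grm_sub <- unclass(sim$grm)[-5, -5]
  Gm <- structure(Gm, class = c("genomic_relationship", "matrix", "array"))
  expect_error(fit_longitudinal(sim$pheno, Gm, model_spec("firmness")),
               "missing from the relationship")
})

test_that("univariate traits fit through the same engine", {
  sim <- quick_sim(seed = 66, n_genotypes = 60, n_checks = 4,
                   time_points = "7W", h2_target = 0.4)
  fit <- fit_longitudinal(sim$pheno, sim$grm, model_spec("firmness", "7W"))
  expect_true(fit$converged)
  h2 <- heritability(fit$components)
  expect_true(h2$h2 >= 0 && h2$h2 <= 1)
  expect_equal(fit$n_params, 2L)
})
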