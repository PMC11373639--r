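test_that("fold partitions are near-equal, seeded and respect always-train ids", {
  ids <- sprintf("g%03d", 1:100)
  f <- make_folds(ids, k = 10, seed = 4)
  expect_equal(unname(table(f)), rep(10L, 10), ignore_attr = TRUE)
  ids101 <- sprintf("g%03d", 1:101)
  f2 <- make_folds(ids101, k = 10, seed = 4)
  expect_lte(diff(range(table(f2))), 1)
  expect_identical(make_folds(ids, 10, 99), make_folds(ids, 10, 99))
  expect_false(identical(make_folds(ids, 10, 99), make_folds(ids, 10, 100)))
  f3 <- make_folds(ids, k = 5, seed = 1, always_train = c("g001", "g002"))
  expect_equal(unname(f3[c("g001", "g002")]), c(0L, 0L))
  expect_error(make_folds(ids[1:5], k = 10, seed = 1), "exceeds")
})

test_that("prediction ability is the Pearson correlation with guards", {
  expect_equal(prediction_ability(1:5, 1:5), 1)
  expect_equal(prediction_ability(1:5, -(1:5)), -1)
  expect_equal(prediction_ability(c(1, 2, 3), c(1, 2, 4)), 0.981980506,
               tolerance = 1e-8)
  expect_error(prediction_ability(1:2, 1:2), ">= 3")
  expect_error(prediction_ability(rep(1, 5), 1:5), "zero variance")
})

test_that("cross-validation never trains on held-out target records", {
  sim <- quick_sim(seed = 91, n_genotypes = 40, n_checks = 4,
                   time_points = c("1D", "7W"))
  spec <- model_spec("firmness", c("1D", "7W"))
  cv1 <- run_cv1(sim$pheno, sim$grm, spec, k = 4, n_repeats = 1, seed = 2,
                 audit = TRUE)
  for (fold in cv1$audit[[1]]) {
    for (id in fold$test_ids) {
      expect_false(any(grepl(paste0("^", id, "\\|"), fold$train_keys)))
    }
  }
  cv2 <- run_cv2(sim$pheno, sim$grm, spec, "1D", "7W", k = 4, n_repeats = 1,
                 seed = 2, audit = TRUE)
  for (fold in cv2$audit[[1]]) {
    for (id in fold$test_ids) {
      own <- fold$train_keys[grepl(paste0("^", id, "\\|"), fold$train_keys)]
      expect_true(all(grepl("\\|1D$", own))) # only known-time records remain
    }
  }
  # checks are never test genotypes
  chk <- unique(sim$pheno$genotype_id[sim$pheno$is_check])
  all_test <- unlist(lapply(cv1$audit[[1]], `[[`, "test_ids"))
  expect_length(intersect(chk, all_test), 0)
})

test_that("cross-validation is reproducible bit for bit under a master seed", {
  sim <- quick_sim(seed = 92, n_genotypes = 36, n_checks = 4,
                   n_markers = 80, n_qtl = 30, time_points = c("1D", "7W"))
  spec <- model_spec("firmness", c("1D", "7W"))
  a <- run_cv1(sim$pheno, sim$grm, spec, k = 4, n_repeats = 2, seed = 11)
  b <- run_cv1(sim$pheno, sim$grm, spec, k = 4, n_repeats = 2, seed = 11)
  expect_identical(a$pa_per_repeat, b$pa_per_repeat)
  c2 <- run_cv1(sim$pheno, sim$grm, spec, k = 4, n_repeats = 2, seed = 12)
  expect_false(identical(a$pa_per_repeat, c2$pa_per_repeat))
})

test_that("CV2 with no known-time records collapses to CV1", {
  sim <- quick_sim(seed = 93, n_genotypes = 40, n_checks = 4,
                   time_points = c("1D", "7W"))
  df <- as.data.frame(sim$pheno)
  # eligible genotypes carry no 1D records at all; checks keep both times
  df <- df[!(df$time_point == "1D" & !df$is_check), ]
  ph <- phenotype_table(df)
  spec <- model_spec("firmness", c("1D", "7W"))
  # CV1 has no eligible 1D records here, so its 1D column is skipped with
  # a warning; the 7W column is what the comparison uses
  cv1 <- suppressWarnings(run_cv1(ph, sim$grm, spec, k = 4, n_repeats = 2,
                                  seed = 6, warm_start = FALSE))
  cv2 <- run_cv2(ph, sim$grm, spec, "1D", "7W", k = 4, n_repeats = 2, seed = 6,
                 warm_start = FALSE)
  expect_equal(cv2$pa_per_repeat, unname(cv1$pa_per_repeat[, "7W"]),
               tolerance = 1e-10)
})

test_that("CV2 validates its time arguments", {
  sim <- quick_sim(seed = 94, n_genotypes = 30, n_checks = 3,
                   n_markers = 60, n_qtl = 20, time_points = c("1D", "7W"))
  spec <- model_spec("firmness", c("1D", "7W"))
  expect_error(run_cv2(sim$pheno, sim$grm, spec, "7W", "7W", k = 3,
                       n_repeats = 1, seed = 1), "strictly earlier")
  expect_error(run_cv2(sim$pheno, sim$grm, spec, "7W", "1D", k = 3,
                       n_repeats = 1, seed = 1), "strictly earlier")
})

test_that("prediction ability grows with heritability on average", {
  pa <- vapply(c(0.15, 0.75), function(h2) {
    sim <- quick_sim(seed = 95, n_genotypes = 70, n_checks = 4,
                     n_markers = 200, n_qtl = 200,
                     time_points = c("1D", "7W"), h2_target = h2)
    cv <- run_cv1(sim$pheno, sim$grm, model_spec("firmness", c("1D", "7W")),
                  k = 5, n_repeats = 2, seed = 3)
    mean(cv$pa_mean)
  }, numeric(1))
  expect_gt(pa[2], pa[1])
})
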