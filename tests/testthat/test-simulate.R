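test_that("generation is deterministic in (base_seed, replicate_index)", {
  sc <- scenario_two_class(k1 = 0.7, mu2 = 1, n = 20, p = 50,
                           n_informative = 10, test_size = 30,
                           base_seed = 5)
  g1 <- generate(sc, 3)
  g2 <- generate(sc, 3)
  expect_identical(g1$train$values, g2$train$values)
  expect_identical(g1$test$values, g2$test$values)
  g3 <- generate(sc, 4)
  expect_false(identical(g1$train$values, g3$train$values))
})

test_that("block-exchangeable correlation structure is reproduced", {
  sc <- nsc_scenario(p = 200, class_sizes = c(2500, 2500),
                     mu_informative = c(0, 0), n_informative = 0,
                     block_size = 100, rho = 0.8, test_size = 4,
                     base_seed = 2)
  g <- generate(sc, 1)
  x <- g$train$values
  within <- cor(x[1, ], x[2, ])
  within2 <- cor(x[150, ], x[199, ])
  across <- cor(x[50, ], x[150, ])
  expect_lt(abs(within - 0.8), 0.02)
  expect_lt(abs(within2 - 0.8), 0.02)
  expect_lt(abs(across), 0.05)
})

test_that("rho = 0 gives essentially uncorrelated variables", {
  sc <- nsc_scenario(p = 20, class_sizes = c(500, 500),
                     mu_informative = c(0, 0), n_informative = 0,
                     rho = 0, test_size = 4, base_seed = 3)
  x <- generate(sc, 1)$train$values
  cm <- cor(t(x))
  offdiag <- cm[upper.tri(cm)]
  expect_lt(mean(abs(offdiag) > 4 / sqrt(1000)), 0.1)
})

test_that("null-case t-statistics follow the standard null", {
  sc <- nsc_scenario(p = 400, class_sizes = c(300, 300),
                     mu_informative = c(0, 0), n_informative = 0,
                     rho = 0, test_size = 4, base_seed = 7)
  g <- generate(sc, 1)
  x <- g$train$values
  y <- g$train$labels
  tstat <- apply(x, 1, function(v) t.test(v[y == 1], v[y == 2])$statistic)
  ks <- suppressWarnings(ks.test(tstat, "pnorm"))
  expect_lt(unname(ks$statistic), 0.08)
  # informative-truth bookkeeping
  expect_equal(sum(g$truth_informative), 0)
})

test_that("class means land on the informative variables only", {
  sc <- scenario_two_class(k1 = 0.5, mu2 = 2, n = 400, p = 60,
                           n_informative = 10, rho = 0, test_size = 10,
                           base_seed = 9)
  g <- generate(sc, 1)
  x <- g$train$values
  y <- g$train$labels
  diffs <- rowMeans(x[, y == 2]) - rowMeans(x[, y == 1])
  expect_true(all(abs(diffs[1:10] - 2) < 0.5))
  expect_true(all(abs(diffs[11:60]) < 0.5))
  expect_equal(g$truth_informative, rep(c(TRUE, FALSE), c(10, 50)))
})

test_that("minority over-sampling balances classes with exact copies", {
  sc <- scenario_two_class(k1 = 0.9, mu2 = 1, n = 100, p = 25,
                           n_informative = 5, test_size = 10,
                           base_seed = 11)
  train <- generate(sc, 1)$train
  os <- oversample_minority(train, seed = 2)
  expect_equal(unname(class_counts(os)), c(90L, 90L))
  expect_equal(os$n, 180L)
  appended <- os$values[, 101:180]
  src <- sub("\\.os[0-9]+$", "", colnames(appended))
  for (i in seq_len(ncol(appended))) {
    expect_identical(unname(appended[, i]), unname(train$values[, src[i]]))
  }
  expect_true(all(os$labels[101:180] == 2L))
  # balanced input returned unchanged
  bal <- make_toy_data(seed = 1)
  expect_identical(oversample_minority(bal), bal)
  # three classes rejected
  expect_error(oversample_minority(make_toy_data(K = 3, seed = 2)),
               "two classes")
})

test_that("run_experiment emits the study-table layout deterministically", {
  sc <- scenario_two_class(k1 = 0.8, mu2 = 2, n = 30, p = 40,
                           n_informative = 10, test_size = 60,
                           base_seed = 13)
  e1 <- run_experiment(sc, methods = "pam", n_replicates = 2,
                       folds = 3, T = 5)
  expect_equal(nrow(e1$replicates), 4)  # 2 replicates x 2 criteria
  expect_equal(nrow(e1$failures), 0)
  expect_true(all(c("replicate", "classifier", "lambda", "pa_1", "pa_2",
                    "gmeans", "auc", "n_active", "fdr", "fnr") %in%
                    names(e1$replicates)))
  expect_setequal(unique(e1$replicates$classifier), c("PAM", "GM-PAM"))
  e2 <- run_experiment(sc, methods = "pam", n_replicates = 2,
                       folds = 3, T = 5)
  expect_equal(e1$replicates, e2$replicates)
  tab <- experiment_table(e1)
  expect_true(all(c("classifier", "n_replicates", "lambda", "lambda_sd",
                    "gmeans", "pct_noninfo") %in% names(tab)))
  pl <- autoplot(e1)
  expect_s3_class(pl, "ggplot")
})

test_that("invalid scenarios are rejected", {
  expect_error(nsc_scenario(p = 10, class_sizes = c(5, 5),
                            mu_informative = c(0, 1), rho = 1),
               "rho")
  expect_error(nsc_scenario(p = 10, class_sizes = c(5, 5),
                            mu_informative = c(0)),
               "one entry per class")
  expect_error(nsc_scenario(p = 10, class_sizes = c(5, 5),
                            mu_informative = c(0, 1),
                            n_informative = 20),
               "informative")
})
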