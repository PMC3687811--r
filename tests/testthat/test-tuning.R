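test_that("threshold grids honor endpoints, spacing and degeneracy", {
  st <- fake_stats(matrix(c(2.9, -1, 0.5, 0.2), 2, 2))
  g2 <- make_grid(st, "pam", T = 2)
  expect_equal(g2$values, c(0, 2.9))
  g30 <- make_grid(st, "pam", T = 30)
  expect_equal(length(g30$values), 30)
  expect_equal(diff(g30$values), rep(0.1, 29), tolerance = 1e-12)
  gl <- make_grid(st, "pam", T = 6, spacing = "log")
  expect_equal(gl$values[1], 0)
  expect_equal(gl$values[6], 2.9)
  expect_true(all(diff(gl$values) > 0))
  expect_warning(make_grid(fake_stats(matrix(0, 1, 2)), "pam"),
                 "degenerate")
  expect_error(make_grid(st, "pam", T = 1), "at least 2")
})

test_that("LOOCV pooled accuracies equal the naive refit-per-sample oracle", {
  d <- make_toy_data(p = 30, n_per_class = 10, shift = 1.2, seed = 23)
  st <- nsc_statistics(d)
  grid <- make_grid(st, "pam", T = 8)
  cv <- cross_validate(d, "pam", grid, folds = d$n, fold_seed = 3)
  ref <- naive_loocv(d, "pam", grid$values)
  # drop the all-tie complete-shrinkage column: its assignment is random
  comparable <- which(grid$values < grid$lambda_max)
  expect_equal(cv$pooled[, comparable], ref[, comparable])
  for (t in comparable) {
    pa_ref <- sapply(1:2, function(k) mean(ref[d$labels == k, t] == k))
    expect_equal(unname(cv$table$pa[[t]]), pa_ref)
  }
})

test_that("threshold selection breaks ties toward the largest threshold", {
  cv <- structure(list(table = tibble::tibble(
    threshold = c(0, 1, 2, 3),
    error = c(0.4, 0.2, 0.2, 0.5),
    gmeans = c(0.5, 0.5, 0.5, 0.5),
    n_active = c(4, 3, 2, 0),
    pa = replicate(4, c(0.5, 0.5), simplify = FALSE))),
    class = "nsc_cv")
  expect_equal(select_threshold(cv, "min_error"), 2)     # tie at 1 and 2
  expect_equal(select_threshold(cv, "max_gmeans"), 3)    # all-equal tie
  cv$table$gmeans <- c(0.2, 0.9, 0.3, 0.1)
  expect_equal(select_threshold(cv, "max_gmeans"), 1)
})

test_that("CV predictions at threshold 0 coincide across the three methods", {
  d <- make_toy_data(p = 20, n_per_class = 8, shift = 1.5, seed = 29)
  grids <- list()
  preds <- list()
  for (meth in c("pam", "alp", "ahp")) {
    st <- nsc_statistics(d)
    w <- adaptive_weights(st)
    g <- make_grid(st, meth, T = 4, weights = w)
    cv <- cross_validate(d, meth, g, folds = 4, fold_seed = 17)
    preds[[meth]] <- cv$pooled[, 1]
  }
  expect_identical(preds$pam, preds$alp)
  expect_identical(preds$pam, preds$ahp)
})

test_that("stratified folds balance class counts within one", {
  set.seed(5)
  labels <- rep(1:2, c(45, 10))
  fid <- gmnsc:::stratified_folds(labels, 5)
  for (k in 1:2) {
    counts <- table(fid[labels == k])
    expect_lte(diff(range(counts)), 1)
  }
})

test_that("folds are reduced with a warning when a class is too small", {
  d <- make_toy_data(p = 10, n_per_class = 4, seed = 31)
  st <- nsc_statistics(d)
  g <- make_grid(st, "pam", T = 3)
  expect_warning(cv <- cross_validate(d, "pam", g, folds = 10,
                                      fold_seed = 1), "reducing folds")
  expect_equal(cv$folds, 4)
})

test_that("pure-noise balanced data give chance-level CV error", {
  set.seed(37)
  x <- matrix(rnorm(40 * 60), 40, 60)
  d <- nsc_data(x, rep(c("a", "b"), each = 30))
  fit <- nsc_fit(d, "pam", "min_error", T = 6, folds = 5, fold_seed = 2)
  expect_lt(abs(mean(fit$cv$table$error) - 0.5), 0.15)
})

test_that("well-separated clusters reach zero error and g-means one", {
  d <- make_toy_data(p = 20, n_per_class = 10, shift = 6, n_signal = 10,
                     seed = 41)
  fit_err <- nsc_fit(d, "pam", "min_error", T = 10, folds = 5,
                     fold_seed = 5)
  fit_gm <- nsc_fit(d, "pam", "max_gmeans", T = 10, folds = 5,
                    fold_seed = 5)
  expect_equal(min(fit_err$cv$table$error), 0)
  expect_equal(max(fit_gm$cv$table$gmeans), 1)
  # on balanced well-separated data the two rules behave alike
  g1 <- glance(fit_err); g2 <- glance(fit_gm)
  expect_equal(g1$cv_error, 0)
  expect_equal(g2$cv_gmeans, 1)
})

test_that("fitting is reproducible given the fold seed", {
  d <- make_toy_data(seed = 43)
  f1 <- nsc_fit(d, "pam", "max_gmeans", T = 6, folds = 4, fold_seed = 11)
  f2 <- nsc_fit(d, "pam", "max_gmeans", T = 6, folds = 4, fold_seed = 11)
  expect_equal(f1$lambda, f2$lambda)
  expect_equal(f1$cv$table$error, f2$cv$table$error)
  x <- matrix(rnorm(d$p * 10), d$p, 10)
  expect_identical(predict(f1, x, rng_seed = 3)$class_index,
                   predict(f2, x, rng_seed = 3)$class_index)
})

test_that("tidy and glance expose the tuning path and summary", {
  d <- make_toy_data(seed = 47)
  fit <- nsc_fit(d, "pam", "max_gmeans", T = 5, folds = 4, fold_seed = 1)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("threshold", "cv_error", "cv_gmeans", "n_active",
                     "cv_pa_1", "cv_pa_2"))
  expect_equal(nrow(td), 5)
  gl <- glance(fit)
  expect_equal(gl$classifier, "GM-PAM")
  expect_true(gl$lambda %in% td$threshold)
  pl <- autoplot(fit)
  expect_s3_class(pl, "ggplot")
})
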