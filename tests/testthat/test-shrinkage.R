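test_that("PAM soft-thresholding matches direct evaluation", {
  st <- fake_stats(matrix(c(2.5, -0.7, 0, 1.0), 2, 2))
  m <- pam_shrink(st, 1.0)
  expect_equal(unname(m$d_hat), matrix(c(1.5, 0, 0, 0), 2, 2))
  # zero threshold is the identity; huge threshold kills everything
  expect_equal(pam_shrink(st, 0)$d_hat, st$d)
  expect_equal(n_active(pam_shrink(st, 2.5)), 0)
  expect_error(pam_shrink(st, -1), "non-negative")
})

test_that("PAM never flips signs nor increases magnitudes", {
  d <- make_toy_data(seed = 2)
  st <- nsc_statistics(d)
  for (lam in c(0.1, 0.5, 1.5)) {
    dh <- pam_shrink(st, lam)$d_hat
    expect_true(all(abs(dh) <= abs(st$d) + 1e-15))
    expect_true(all(dh == 0 | sign(dh) == sign(st$d)))
  }
})

test_that("ALP clips only components above the common cap", {
  st <- fake_stats(matrix(c(3, 1), 1, 2))
  m <- alp_shrink(st, 0.5, weights = 1)
  expect_equal(unname(m$d_hat), matrix(c(2.5, 1), 1, 2))
  # boundary of the all-zero condition: sum |d| = lambda * w
  m0 <- alp_shrink(st, 4, weights = 1)
  expect_equal(unname(m0$d_hat), matrix(0, 1, 2))
  expect_equal(alp_shrink(st, 0, weights = 1)$d_hat, st$d)
  expect_error(alp_shrink(st, 0.5, weights = -1), "positive")
})

test_that("ALP per-variable solutions match the numeric oracle", {
  set.seed(21)
  worst <- 0
  for (i in 1:120) {
    K <- sample(2:4, 1)
    dcol <- rnorm(K, sd = 2) * rbinom(K, 1, 0.85)
    lam <- runif(1, 0, 3)
    w <- runif(1, 0.3, 2)
    st <- fake_stats(matrix(dcol, 1, K))
    v <- as.numeric(alp_shrink(st, lam, weights = w)$d_hat)
    pen <- list(type = "alp", lambda = lam, weight = w)
    o <- pergene_numeric_oracle(dcol, pen)
    worst <- max(worst, pergene_objective(v, dcol, pen) -
                   attr(o, "objective"))
    # components strictly below the cap come back unchanged
    cap <- max(abs(v))
    below <- abs(dcol) < cap - 1e-9
    expect_equal(v[below], dcol[below])
  }
  expect_lt(worst, 1e-6)
})

test_that("AHP solutions match a dense grid search on small instances", {
  set.seed(31)
  for (i in 1:2) {
    dcol <- rnorm(2, sd = 2)
    lt <- runif(1, 0.2, 1); lg <- runif(1, 0.2, 1)
    wg <- runif(1, 0.5, 1.5); wt <- runif(2, 0.5, 1.5)
    st <- fake_stats(matrix(dcol, 1, 2))
    v <- as.numeric(ahp_shrink(st, lt, lg,
                               weights = list(ahp_gamma = wg,
                                              ahp_theta = matrix(wt, 1, 2)))$d_hat)
    obj_impl <- 0.5 * sum((v - dcol)^2) +
      if (all(v == 0)) 0 else {
        # profiled penalty at the returned product
        2 * sqrt(lg * wg * lt * sum(wt * abs(v)))
      }
    # literal dense grid over (gamma, theta1, theta2)
    gam <- seq(0.01, 3 * max(abs(dcol)), length.out = 60)
    th <- seq(-1.5 * max(abs(dcol)), 1.5 * max(abs(dcol)), length.out = 61)
    gr <- expand.grid(g = gam, t1 = th, t2 = th)
    obj <- 0.5 * ((gr$g * gr$t1 - dcol[1])^2 + (gr$g * gr$t2 - dcol[2])^2) +
      lg * wg * gr$g + lt * (wt[1] * abs(gr$t1) + wt[2] * abs(gr$t2))
    best_grid <- min(min(obj), 0.5 * sum(dcol^2))
    # coarse grid cannot beat the solver by more than its own resolution
    expect_lt(obj_impl, best_grid + 1e-3)
  }
})

test_that("AHP per-variable objectives match the numeric oracle", {
  set.seed(41)
  worst <- 0
  for (i in 1:120) {
    K <- sample(2:4, 1)
    dcol <- rnorm(K, sd = 2) * rbinom(K, 1, 0.85)
    lt <- runif(1, 0, 2); lg <- runif(1, 0, 2)
    wg <- runif(1, 0.3, 2); wt <- runif(K, 0.3, 2)
    st <- fake_stats(matrix(dcol, 1, K))
    v <- as.numeric(ahp_shrink(st, lt, lg,
                               weights = list(ahp_gamma = wg,
                                              ahp_theta = matrix(wt, 1, K)))$d_hat)
    pen <- list(type = "ahp", lambda = lt, lambda_gamma = lg,
                w_gamma = wg, w_theta = wt)
    o <- pergene_numeric_oracle(dcol, pen)
    worst <- max(worst, pergene_objective(v, dcol, pen) -
                   attr(o, "objective"))
  }
  expect_lt(worst, 1e-6)
})

test_that("AHP trivial limits: zero lambdas and zero input", {
  st <- fake_stats(matrix(c(1.2, -0.4, 0, 0), 2, 2))
  expect_equal(ahp_shrink(st, 0, 0)$d_hat, st$d)
  m <- ahp_shrink(st, 0.8)
  expect_equal(unname(m$d_hat[2, ]), c(0, 0))  # zero column stays zero
})

test_that("lambda_max is exact for PAM/ALP and the boundary holds for all", {
  st1 <- fake_stats(matrix(c(0, 2, 0, 0), 2, 2))
  expect_equal(lambda_max(st1, "pam"), 2)
  st2 <- fake_stats(matrix(c(3, 0, 1, 0), 2, 2))
  expect_equal(lambda_max(st2, "alp",
                          weights = list(alp = c(1, 1))), 4)

  d <- make_toy_data(p = 15, seed = 6)
  st <- nsc_statistics(d)
  w <- adaptive_weights(st)
  for (meth in c("pam", "alp", "ahp")) {
    lm <- lambda_max(st, meth, weights = w)
    expect_equal(n_active(nsc_shrink(st, meth, lm, weights = w)), 0)
    expect_gte(n_active(nsc_shrink(st, meth, lm * (1 - 1e-6),
                                   weights = w)), 1)
  }
  # all-zero d matrix
  expect_equal(lambda_max(fake_stats(matrix(0, 2, 2)), "pam"), 0)
})

test_that("AHP lambda_max agrees with bisection on the numeric oracle", {
  set.seed(51)
  for (i in 1:4) {
    K <- 3
    dcol <- rnorm(K)
    wg <- runif(1, 0.5, 1.5); wt <- runif(K, 0.5, 1.5)
    st <- fake_stats(matrix(dcol, 1, K))
    w <- list(ahp_gamma = wg, ahp_theta = matrix(wt, 1, K))
    lm <- lambda_max(st, "ahp", weights = w)
    is_zero <- function(lam) {
      pen <- list(type = "ahp", lambda = lam, lambda_gamma = lam,
                  w_gamma = wg, w_theta = wt)
      o <- pergene_numeric_oracle(dcol, pen)
      max(abs(o)) < 1e-6
    }
    lo <- 1e-4; hi <- 10 * lm + 1
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (is_zero(mid)) hi <- mid else lo <- mid
    }
    expect_equal(lm, hi, tolerance = 1e-3)
  }
})

test_that("active-variable count is non-increasing in the threshold", {
  d <- make_toy_data(p = 40, seed = 8)
  st <- nsc_statistics(d)
  w <- adaptive_weights(st)
  for (meth in c("pam", "alp", "ahp")) {
    lm <- lambda_max(st, meth, weights = w)
    lams <- seq(0, lm, length.out = 8)
    counts <- sapply(lams, function(l) {
      n_active(nsc_shrink(st, meth, l, weights = w))
    })
    expect_true(all(diff(counts) <= 0))
    expect_equal(counts[1], st$p)   # generic data: all active at 0
    expect_equal(counts[8], 0)
  }
})

test_that("the numeric oracle itself reproduces known closed forms", {
  set.seed(61)
  # lasso penalty: soft threshold
  for (i in 1:25) {
    dcol <- rnorm(3, sd = 2)
    lam <- runif(1, 0, 2)
    o <- pergene_numeric_oracle(dcol, list(type = "pam", lambda = lam))
    expect_equal(as.numeric(o), sign(dcol) * pmax(abs(dcol) - lam, 0),
                 tolerance = 1e-5)
  }
  # L-infinity penalty limits
  dcol <- c(1.5, -0.5)
  o0 <- pergene_numeric_oracle(dcol, list(type = "alp", lambda = 0,
                                          weight = 1))
  expect_equal(as.numeric(o0), dcol, tolerance = 1e-6)
  ohuge <- pergene_numeric_oracle(dcol, list(type = "alp", lambda = 100,
                                             weight = 1))
  expect_equal(as.numeric(ohuge), c(0, 0), tolerance = 1e-6)
})
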