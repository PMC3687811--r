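# Independent oracles used across the test files. These deliberately use
# explicit loops / brute force and never call the production code paths
# they are checking.

# centroid statistics recomputed from first principles with loops
oracle_statistics <- function(values, labels) {
  p <- nrow(values); n <- ncol(values)
  classes <- sort(unique(labels))
  K <- length(classes)
  n_k <- unname(sapply(classes, function(k) sum(labels == k)))
  centroids <- matrix(NA_real_, p, K)
  for (k in seq_len(K)) {
    for (j in seq_len(p)) {
      centroids[j, k] <- mean(values[j, labels == classes[k]])
    }
  }
  overall <- apply(values, 1, mean)
  pooled_sd <- numeric(p)
  for (j in seq_len(p)) {
    ss <- 0
    for (i in seq_len(n)) {
      k <- match(labels[i], classes)
      ss <- ss + (values[j, i] - centroids[j, k])^2
    }
    pooled_sd[j] <- sqrt(ss / (n - K))
  }
  s0 <- median(pooled_sd)
  m <- sqrt(1 / n_k - 1 / n)
  d <- matrix(NA_real_, p, K)
  for (k in seq_len(K)) {
    for (j in seq_len(p)) {
      d[j, k] <- (centroids[j, k] - overall[j]) /
        (m[k] * (pooled_sd[j] + s0))
    }
  }
  list(centroids = centroids, overall = overall, pooled_sd = pooled_sd,
       s0 = s0, m = m, d = d)
}

# discriminant scores evaluated term by term
oracle_delta <- function(x, centroids, pooled_sd, s0, priors) {
  K <- ncol(centroids)
  sapply(seq_len(K), function(k) {
    sum((x - centroids[, k])^2 / (pooled_sd + s0)^2) - 2 * log(priors[k])
  })
}

# AUC by O(n^2) pairwise comparison, half credit for ties
auc_pairwise <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  total <- 0
  for (sp in pos) {
    for (sn in neg) {
      total <- total + (sp > sn) + 0.5 * (sp == sn)
    }
  }
  total / (length(pos) * length(neg))
}

# leave-one-out CV by refitting from scratch for every held-out sample
naive_loocv <- function(data, method, thresholds) {
  n <- data$n
  pred <- matrix(NA_integer_, n, length(thresholds))
  for (i in seq_len(n)) {
    tr <- gmnsc:::subset_samples(data, setdiff(seq_len(n), i))
    st <- nsc_statistics(tr)
    w <- if (method == "pam") NULL else adaptive_weights(st)
    for (t in seq_along(thresholds)) {
      model <- nsc_shrink(st, method, thresholds[t], weights = w)
      delta <- discriminant_scores(model, data$values[, i], "equal")
      pred[i, t] <- which.min(delta)
    }
  }
  pred
}

# a hand-assembled nsc_statistics whose d matrix is exactly `d`:
# pooled_sd + s0 = 1 and m = 1, so shrunken centroids equal d_hat
fake_stats <- function(d) {
  p <- nrow(d); K <- ncol(d)
  structure(
    list(centroids = d, overall = rep(0, p), pooled_sd = rep(0.5, p),
         s0 = 0.5, m = rep(1, K), d = d, n_k = rep(10L, K), n = 10L * K,
         K = K, p = p, class_levels = as.character(seq_len(K)),
         variable_ids = paste0("V", seq_len(p))),
    class = "nsc_statistics")
}

# small labeled dataset with a controllable signal
make_toy_data <- function(p = 30, n_per_class = 10, K = 2, shift = 2,
                          n_signal = 5, seed = 1) {
  set.seed(seed)
  n_signal <- min(n_signal, p)
  n <- n_per_class * K
  x <- matrix(rnorm(p * n), p, n)
  labels <- rep(seq_len(K), each = n_per_class)
  for (k in seq_len(K)[-1]) {
    x[seq_len(n_signal), labels == k] <-
      x[seq_len(n_signal), labels == k] + shift * (k - 1)
  }
  nsc_data(x, as.character(labels))
}
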