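#' Centroid statistics for nearest shrunken centroid classifiers
#'
#' Computes every sufficient statistic the NSC family needs from labeled
#' expression data: class centroids \eqn{\bar x_{kj}}, the overall centroid
#' \eqn{\bar x_j} (mean over all samples, so a sample-size-weighted average
#' of the class centroids), the pooled within-class standard deviation
#' \eqn{s_j} (divisor \eqn{n-K}), the fudge constant \eqn{s_0} (median of
#' the \eqn{s_j}), the standard-error factors
#' \eqn{m_k = \sqrt{1/n_k - 1/n}} and the standardized centroid differences
#' \deqn{d_{kj} = \frac{\bar x_{kj} - \bar x_j}{m_k (s_j + s_0)},}
#' the quantity all three shrinkage penalties operate on.
#'
#' @param data an [nsc_data] object; every class must have at least two
#'   samples (the pooled SD needs within-class residuals).
#'
#' @return An object of class `nsc_statistics`: list with `centroids`
#'   (p x K), `overall` (length p), `pooled_sd` (length p), `s0` (scalar),
#'   `m` (length K), `d` (p x K), `n_k`, `n`, `K`, `p`, `class_levels`,
#'   `variable_ids`.
#'
#' @examples
#' d <- nsc_data(matrix(rnorm(40), 10, 4), c(1, 1, 2, 2))
#' s <- nsc_statistics(d)
#' range(s$d)
#' @export
nsc_statistics <- function(data) {
  stopifnot(inherits(data, "nsc_data"))
  n <- data$n
  K <- data$K
  p <- data$p
  n_k <- tabulate(data$labels, nbins = K)
  small <- which(n_k < 2L)
  if (length(small) > 0L) {
    stop(sprintf("class '%s' has %d sample(s); at least 2 are required",
                 data$class_levels[small[1L]], n_k[small[1L]]))
  }

  X <- data$values
  # indicator matrix n x K; class sums via one matrix product
  Z <- matrix(0, n, K)
  Z[cbind(seq_len(n), data$labels)] <- 1
  centroids <- (X %*% Z) %*% diag(1 / n_k, K)   # p x K
  overall <- rowMeans(X)

  # pooled within-class SS: sum_i x^2 - sum_k n_k xbar_k^2, divisor n - K
  ss_within <- rowSums(X^2) - drop(centroids^2 %*% n_k)
  pooled_sd <- sqrt(pmax(ss_within, 0) / (n - K))
  s0 <- stats::median(pooled_sd)
  if (any(pooled_sd + s0 == 0)) {
    stop("zero pooled standard deviation with s0 = 0 (constant variables); ",
         "d_kj is undefined (division by zero)")
  }

  m <- sqrt(1 / n_k - 1 / n)
  denom <- pooled_sd + s0                      # length p
  d <- sweep(centroids - overall, 1, denom, "/")
  d <- sweep(d, 2, m, "/")

  dimnames(centroids) <- list(rownames(X), data$class_levels)
  dimnames(d) <- dimnames(centroids)
  structure(
    list(centroids = centroids, overall = overall, pooled_sd = pooled_sd,
         s0 = s0, m = m, d = d, n_k = n_k, n = n, K = K, p = p,
         class_levels = data$class_levels, variable_ids = rownames(X)),
    class = "nsc_statistics"
  )
}

#' @export
print.nsc_statistics <- function(x, ...) {
  cat(sprintf("<nsc_statistics> p=%d, K=%d, n=%d; s0=%.4g; max|d|=%.4g\n",
              x$p, x$K, x$n, x$s0, max(abs(x$d))))
  invisible(x)
}

#' Shrunken centroids from shrunken differences
#'
#' Inverts the standardization: given shrunken differences
#' \eqn{\hat d_{kj}}, reconstructs the class centroids
#' \eqn{\bar x'_{kj} = \bar x_j + \hat d_{kj}\, m_k (s_j + s_0)}.
#' With `d_hat = stats$d` this reproduces the raw class centroids; with
#' `d_hat = 0` every centroid collapses onto the overall centroid.
#'
#' @param stats an [nsc_statistics] object.
#' @param d_hat p x K numeric matrix of shrunken differences.
#' @return p x K matrix of shrunken centroids.
#' @export
shrunken_centroids <- function(stats, d_hat) {
  stopifnot(inherits(stats, "nsc_statistics"))
  if (!is.matrix(d_hat) || nrow(d_hat) != stats$p || ncol(d_hat) != stats$K) {
    stop(sprintf("`d_hat` must be a %d x %d matrix", stats$p, stats$K))
  }
  if (any(!is.finite(d_hat))) stop("`d_hat` must be finite")
  sc <- sweep(d_hat, 1, stats$pooled_sd + stats$s0, "*")
  sc <- sweep(sc, 2, stats$m, "*")
  sc <- sc + stats$overall
  dimnames(sc) <- dimnames(stats$centroids)
  sc
}
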