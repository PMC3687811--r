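#' Adaptive penalty weights
#'
#' Data-driven weights in the adaptive-LASSO spirit: variables whose
#' standardized centroid differences are large are penalized less. The
#' conventions are \eqn{w_j = 1/\max_k |d_{kj}|} for the ALP penalty,
#' \eqn{w^\gamma_j = 1/\max_k |d_{kj}|} for the AHP variable-level factor
#' and \eqn{w^\theta_{kj} = 1/|d_{kj}|} for the AHP class-level factors,
#' all clamped at `1/eps` when the denominator is near zero.
#'
#' @param stats an [nsc_statistics] object.
#' @param eps clamp for near-zero denominators (default `1e-8`).
#' @return list with `alp` (length p), `ahp_gamma` (length p) and
#'   `ahp_theta` (p x K matrix), all strictly positive and finite.
#' @export
adaptive_weights <- function(stats, eps = 1e-8) {
  stopifnot(inherits(stats, "nsc_statistics"))
  a <- abs(stats$d)
  amax <- apply(a, 1, max)
  list(
    alp = 1 / pmax(amax, eps),
    ahp_gamma = 1 / pmax(amax, eps),
    ahp_theta = 1 / pmax(a, eps)
  )
}

new_nsc_model <- function(stats, method, d_hat, threshold, weights = NULL) {
  active <- rowSums(d_hat != 0) > 0
  structure(
    list(method = method, threshold = threshold, d_hat = d_hat,
         centroids = shrunken_centroids(stats, d_hat), active = active,
         weights = weights, stats = stats),
    class = "nsc_model"
  )
}

#' @export
print.nsc_model <- function(x, ...) {
  thr <- paste(sprintf("%.4g", unlist(x$threshold)), collapse = "/")
  cat(sprintf("<nsc_model> method=%s, threshold=%s, active=%d/%d variables\n",
              x$method, thr, sum(x$active), x$stats$p))
  invisible(x)
}

#' Number of active variables of a shrunken model
#'
#' A variable is active when at least one of its shrunken centroids differs
#' from the overall centroid, i.e. \eqn{\hat d_{kj} \ne 0} for some class.
#' @param model an `nsc_model`.
#' @return integer count.
#' @export
n_active <- function(model) {
  stopifnot(inherits(model, "nsc_model"))
  sum(model$active)
}

#' PAM shrinkage: uniform soft-thresholding
#'
#' Applies the soft-threshold operator
#' \eqn{\hat d_{kj} = \mathrm{sgn}(d_{kj}) (|d_{kj}| - \lambda)_+}
#' to every standardized difference, so all variables are shrunken by the
#' same amount.
#'
#' @param stats an [nsc_statistics] object.
#' @param lambda threshold, a single number `>= 0`.
#' @return an `nsc_model`.
#' @export
pam_shrink <- function(stats, lambda) {
  stopifnot(inherits(stats, "nsc_statistics"))
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0) {
    stop("`lambda` must be a single non-negative number")
  }
  d_hat <- sign(stats$d) * pmax(abs(stats$d) - lambda, 0)
  new_nsc_model(stats, "pam", d_hat, list(lambda = lambda))
}

# prox of lambda_j * max_k |.| per variable, vectorised across variables.
# Solution clips |d_kj| at a common cap c_j with
# sum_k (|d_kj| - c_j)_+ = lambda_j, and is all-zero iff
# sum_k |d_kj| <= lambda_j.
alp_prox <- function(d, lam) {
  p <- nrow(d); K <- ncol(d)
  A <- abs(d)
  As <- matrix(A[order(row(A), -A)], nrow = p, byrow = TRUE)  # row-sorted desc
  CS <- As %*% upper.tri(matrix(0, K, K), diag = TRUE)        # row cumsums
  Ci <- (CS - lam) / rep(seq_len(K), each = p)
  istar <- rowSums(As > Ci)
  zero <- CS[, K] <= lam
  cap <- ifelse(zero, 0,
                (CS[cbind(seq_len(p), pmax(istar, 1L))] - lam) /
                  pmax(istar, 1L))
  cap <- pmax(cap, 0)
  sign(d) * pmin(A, cap)
}

#' ALP shrinkage: adaptive L-infinity-norm penalty
#'
#' For every variable `j` independently, solves
#' \deqn{\min_v \tfrac12 \sum_k (v_k - d_{kj})^2 +
#'       \lambda w_j \max_k |v_k|.}
#' The solution clips the components at a common cap: components with
#' \eqn{|d_{kj}|} below the cap are untouched, larger ones are pulled down
#' to it, and the variable drops out entirely
#' (\eqn{\hat d_{\cdot j} = 0}) iff \eqn{\sum_k |d_{kj}| \le \lambda w_j}.
#'
#' @param stats an [nsc_statistics] object.
#' @param lambda threshold `>= 0`.
#' @param weights positive per-variable weights \eqn{w_j}; defaults to the
#'   adaptive weights of [adaptive_weights()].
#' @return an `nsc_model`.
#' @export
alp_shrink <- function(stats, lambda, weights = NULL) {
  stopifnot(inherits(stats, "nsc_statistics"))
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0) {
    stop("`lambda` must be a single non-negative number")
  }
  if (is.null(weights)) weights <- adaptive_weights(stats)$alp
  if (length(weights) != stats$p || any(!is.finite(weights)) ||
      any(weights <= 0)) {
    stop("`weights` must be p strictly positive finite numbers")
  }
  d_hat <- if (lambda == 0) stats$d else alp_prox(stats$d, lambda * weights)
  new_nsc_model(stats, "alp", d_hat, list(lambda = lambda),
                weights = list(alp = weights))
}

# one run of the alternating AHP solver from a given gamma start,
# vectorised across variables. Returns d_hat, per-variable objective and
# convergence flags.
ahp_alternate <- function(d, lt, lg, wg, wt, gamma0, tol = 1e-8,
                          maxit = 2000L) {
  p <- nrow(d); K <- ncol(d)
  gamma <- pmax(gamma0, 0)
  Theta <- matrix(0, p, K)
  obj <- rep(Inf, p)
  converged <- rep(FALSE, p)
  alive <- gamma > 0
  for (it in seq_len(maxit)) {
    g <- pmax(gamma, .Machine$double.eps)
    thr <- (lt * wt) / g
    U <- sign(d) * pmax(abs(d) - thr, 0)   # U = gamma * theta
    Theta <- U / g
    Theta[!alive, ] <- 0
    num <- rowSums(Theta * d) - lg * wg
    den <- rowSums(Theta^2)
    gamma <- ifelse(alive & den > 0, pmax(num / den, 0), 0)
    alive <- alive & gamma > 0
    fit <- sweep(Theta, 1, gamma, "*")
    obj_new <- 0.5 * rowSums((fit - d)^2) + lg * wg * gamma +
      lt * rowSums(wt * abs(Theta))
    obj_new[!alive] <- 0.5 * rowSums(d^2)[!alive]
    newly <- !converged & is.finite(obj_new) & abs(obj - obj_new) < tol
    converged <- converged | newly | !alive
    obj <- pmin(obj, obj_new)
    if (all(converged)) break
  }
  fit <- sweep(Theta, 1, gamma, "*")
  fit[!alive, ] <- 0
  list(d_hat = fit, objective = obj, converged = converged)
}

#' AHP shrinkage: adaptive hierarchical penalty
#'
#' Decomposes each standardized difference as
#' \eqn{\tilde d_{kj} = \gamma_j \theta_{kj}} with a non-negative
#' variable-level factor and class-level factors, penalized separately:
#' \deqn{\min_{\gamma_j \ge 0,\ \theta_{\cdot j}} \tfrac12 \sum_k
#'   (\gamma_j \theta_{kj} - d_{kj})^2 +
#'   \lambda_\gamma w^\gamma_j \gamma_j +
#'   \lambda_\theta \sum_k w^\theta_{kj} |\theta_{kj}|.}
#' Solved per variable by alternating closed-form updates (soft-threshold
#' \eqn{\theta}-step, non-negative least-squares \eqn{\gamma}-step), run
#' from several \eqn{\gamma} starting points and compared against the
#' all-zero solution; only the product \eqn{\hat d_{kj} =
#' \gamma_j \theta_{kj}} is returned, so the scale ambiguity of the
#' factorization is immaterial.
#'
#' @param stats an [nsc_statistics] object.
#' @param lambda_theta class-level threshold \eqn{\lambda_\theta \ge 0};
#'   this is the tuned threshold.
#' @param lambda_gamma variable-level threshold; defaults to
#'   `lambda_theta` (one-dimensional tuning path).
#' @param weights list with components `ahp_gamma` (length p) and
#'   `ahp_theta` (p x K); defaults to [adaptive_weights()].
#' @param tol convergence tolerance on the per-variable objective decrease.
#' @param maxit maximum alternating iterations, default 2000 (error if
#'   exceeded; convergence is sublinear when a threshold is very small).
#' @return an `nsc_model` (threshold holds both lambdas).
#' @export
ahp_shrink <- function(stats, lambda_theta, lambda_gamma = lambda_theta,
                       weights = NULL, tol = 1e-8, maxit = 2000L) {
  stopifnot(inherits(stats, "nsc_statistics"))
  if (!is.finite(lambda_theta) || lambda_theta < 0 ||
      !is.finite(lambda_gamma) || lambda_gamma < 0) {
    stop("both lambdas must be non-negative finite numbers")
  }
  if (is.null(weights)) {
    w <- adaptive_weights(stats)
    weights <- list(ahp_gamma = w$ahp_gamma, ahp_theta = w$ahp_theta)
  }
  wg <- weights$ahp_gamma
  wt <- weights$ahp_theta
  if (length(wg) != stats$p || any(wg <= 0) ||
      !is.matrix(wt) || any(dim(wt) != c(stats$p, stats$K)) || any(wt <= 0)) {
    stop("AHP weights must be strictly positive with shapes p and p x K")
  }
  thr <- list(lambda_theta = lambda_theta, lambda_gamma = lambda_gamma)
  if (lambda_theta == 0 || lambda_gamma == 0) {
    # either factor unpenalized: the scale ambiguity lets the other
    # penalty term vanish in the limit, so the minimizer is d itself
    return(new_nsc_model(stats, "ahp", stats$d, thr, weights = weights))
  }

  d <- stats$d
  amax <- apply(abs(d), 1, max)
  zero_obj <- 0.5 * rowSums(d^2)
  best <- list(d_hat = matrix(0, stats$p, stats$K), objective = zero_obj,
               converged = rep(TRUE, stats$p))
  for (scale in c(1, 0.25, 4)) {
    run <- ahp_alternate(d, lambda_theta, lambda_gamma, wg, wt,
                         gamma0 = scale * amax, tol = tol, maxit = maxit)
    better <- run$objective < best$objective - 1e-12
    best$d_hat[better, ] <- run$d_hat[better, , drop = FALSE]
    best$converged[better] <- run$converged[better]
    best$objective <- pmin(best$objective, run$objective)
  }
  if (!all(best$converged)) {
    stop(sprintf("AHP solver did not converge for variable %d within %d iterations",
                 which(!best$converged)[1L], maxit))
  }
  dimnames(best$d_hat) <- dimnames(d)
  new_nsc_model(stats, "ahp", best$d_hat, thr, weights = weights)
}

#' Shrink by method name
#'
#' Thin dispatcher used by the tuning loop: applies the PAM, ALP or AHP
#' penalty at a given threshold with the supplied (or default adaptive)
#' weights. For AHP the single threshold is used for both
#' \eqn{\lambda_\theta} and \eqn{\lambda_\gamma \cdot} `lambda_ratio`.
#'
#' @param stats an [nsc_statistics] object.
#' @param method `"pam"`, `"alp"` or `"ahp"`.
#' @param lambda threshold `>= 0`.
#' @param weights optional weights list as returned by [adaptive_weights()].
#' @param lambda_ratio AHP only: \eqn{\lambda_\gamma / \lambda_\theta}
#'   (default 1).
#' @return an `nsc_model`.
#' @export
nsc_shrink <- function(stats, method, lambda, weights = NULL,
                       lambda_ratio = 1) {
  method <- match.arg(method, c("pam", "alp", "ahp"))
  switch(method,
    pam = pam_shrink(stats, lambda),
    alp = alp_shrink(stats, lambda, weights = weights$alp),
    ahp = ahp_shrink(stats, lambda, lambda_gamma = lambda_ratio * lambda,
                     weights = weights)
  )
}

#' Complete-shrinkage threshold
#'
#' The smallest threshold at which every class centroid collapses onto the
#' overall centroid (zero active variables). Closed forms:
#' PAM \eqn{\lambda_{max} = \max_{k,j} |d_{kj}|}; ALP
#' \eqn{\lambda_{max} = \max_j \sum_k |d_{kj}| / w_j}. For AHP the
#' per-variable all-zero condition, after profiling out \eqn{\theta} and
#' substituting \eqn{t = \gamma/\lambda}, reduces to
#' \deqn{\lambda_j^2 = \max_{t>0} \frac{\sum_k ((t\,|d_{kj}| -
#'   w^\theta_{kj})_+)^2}{2\, r\, w^\gamma_j\, t^3}}
#' with \eqn{r = \lambda_\gamma/\lambda_\theta}; the maximization is solved
#' exactly piecewise (the stationary point on each piece is the root of a
#' quadratic) and \eqn{\lambda_{max} = \max_j \lambda_j}.
#'
#' @inheritParams nsc_shrink
#' @return a single non-negative number; 0 when all `d` are zero.
#' @export
lambda_max <- function(stats, method, weights = NULL, lambda_ratio = 1) {
  stopifnot(inherits(stats, "nsc_statistics"))
  method <- match.arg(method, c("pam", "alp", "ahp"))
  A <- abs(stats$d)
  if (all(A == 0)) return(0)
  if (method == "pam") return(max(A))
  if (is.null(weights)) weights <- adaptive_weights(stats)
  if (method == "alp") {
    return(max(rowSums(A) / weights$alp))
  }
  wg <- weights$ahp_gamma
  wt <- weights$ahp_theta
  lam2 <- vapply(seq_len(stats$p), function(j) {
    ahp_lambda2_gene(A[j, ], wt[j, ], wg[j], lambda_ratio)
  }, numeric(1))
  sqrt(max(lam2))
}

# max_t sum_k((t a_k - w_k)_+)^2 / (2 r wg t^3) for one variable, solved
# piecewise over the breakpoints t_k = w_k / a_k.
ahp_lambda2_gene <- function(a, w, wg, r) {
  keep <- a > 0
  if (!any(keep)) return(0)
  a <- a[keep]; w <- w[keep]
  ord <- order(w / a)
  a <- a[ord]; w <- w[ord]
  b <- w / a                      # ascending breakpoints
  K <- length(a)
  psi <- function(t, i) sum((t * a[seq_len(i)] - w[seq_len(i)])^2) / t^3
  best <- 0
  for (i in seq_len(K)) {
    lo <- b[i]
    hi <- if (i < K) b[i + 1L] else Inf
    A2 <- sum(a[seq_len(i)]^2)
    B <- sum(a[seq_len(i)] * w[seq_len(i)])
    C2 <- sum(w[seq_len(i)]^2)
    disc <- 4 * B^2 - 3 * A2 * C2
    if (disc >= 0) {
      tstar <- (2 * B + sqrt(disc)) / A2   # the local max of psi on the piece
      if (tstar > lo && tstar <= hi) best <- max(best, psi(tstar, i))
    }
    if (is.finite(hi)) best <- max(best, psi(hi, i))
  }
  best / (2 * r * wg)
}

#' Per-variable objective of the penalized least-squares subproblem
#'
#' The criterion each penalty minimizes for one variable:
#' \eqn{\tfrac12\sum_k (v_k - d_k)^2} plus, depending on the descriptor,
#' the lasso (`pam`), the weighted L-infinity (`alp`) or the profiled
#' hierarchical penalty \eqn{2\sqrt{\lambda_\gamma w^\gamma \lambda_\theta
#' \sum_k w^\theta_k |v_k|}} (`ahp`; exact profile over the
#' \eqn{(\gamma,\theta)} factorization at fixed product).
#'
#' @param v candidate solution, length K.
#' @param d_col observed standardized differences, length K.
#' @param penalty list: `type` in `"pam"`/`"alp"`/`"ahp"`; `lambda`; `alp`
#'   additionally `weight` (scalar); `ahp` additionally `lambda_gamma`,
#'   `w_gamma` (scalar) and `w_theta` (length K).
#' @return the objective value, a single number.
#' @export
pergene_objective <- function(v, d_col, penalty) {
  loss <- 0.5 * sum((v - d_col)^2)
  pen <- switch(penalty$type,
    pam = penalty$lambda * sum(abs(v)),
    alp = penalty$lambda * penalty$weight * max(abs(v)),
    ahp = 2 * sqrt(penalty$lambda_gamma * penalty$w_gamma *
                     penalty$lambda * sum(penalty$w_theta * abs(v))),
    stop("unknown penalty type")
  )
  loss + pen
}

#' Brute-force per-variable solver (test oracle)
#'
#' Minimizes the per-variable penalized objective by multi-start
#' Nelder-Mead over the K-dimensional solution, independent of the
#' closed-form / alternating routes used by the shrinkage functions. Meant
#' for small K (tests); returns the best solution found with its objective
#' attached as an attribute.
#'
#' @inheritParams pergene_objective
#' @return numeric vector of length K with attribute `"objective"`.
#' @export
pergene_numeric_oracle <- function(d_col, penalty) {
  K <- length(d_col)
  if (K > 5L) stop("oracle is intended for K <= 5")
  f <- function(v) pergene_objective(v, d_col, penalty)
  lam <- penalty$lambda
  starts <- list(d_col, rep(0, K), d_col / 2,
                 sign(d_col) * pmax(abs(d_col) - lam, 0),
                 sign(d_col) * pmax(abs(d_col) - lam / 2, 0))
  for (i in 1:4) starts <- c(starts, list(d_col * stats::runif(1, 0, 1)))
  best_v <- rep(0, K); best <- f(best_v)
  for (s in starts) {
    v <- s
    if (K == 1L) {
      opt <- stats::optimize(function(z) f(z),
                             interval = range(c(-abs(d_col) - 1, abs(d_col) + 1)))
      v <- opt$minimum
    } else {
      for (round in 1:2) {
        res <- stats::optim(v, f, method = "Nelder-Mead",
                            control = list(maxit = 5000, reltol = 1e-14))
        v <- res$par
      }
    }
    if (f(v) < best) { best <- f(v); best_v <- v }
  }
  attr(best_v, "objective") <- best
  best_v
}
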