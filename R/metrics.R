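#' Geometric mean of class-specific predictive accuracies
#'
#' \eqn{GM = (\prod_k PA_k)^{1/K}}: gives every class the same weight
#' regardless of the test-set composition, penalizes heterogeneous
#' performance and, for a fixed sum of accuracies, is maximal when they are
#' all equal. It is 0 whenever any class is never predicted correctly.
#'
#' @param pa numeric vector of per-class accuracies in `[0, 1]`.
#' @return a single number in `[0, 1]`.
#' @export
gmeans <- function(pa) {
  if (any(pa < 0 | pa > 1)) stop("accuracies must lie in [0, 1]")
  if (any(pa == 0)) return(0)
  exp(mean(log(pa)))
}

#' Rank-based AUC (Mann-Whitney, half credit for ties)
#'
#' @param scores numeric scores, larger meaning more positive-like.
#' @param positive logical vector, `TRUE` for the positive class.
#' @return AUC in `[0, 1]`; `NA` if either class is empty.
#' @export
auc_rank <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)                       # average ranks = half-credit ties
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a shrunken model on an independent test set
#'
#' Computes the per-class predictive accuracies, the overall accuracy
#' (weighted by the empirical test-set class fractions, i.e. one minus the
#' pooled misclassification rate), their geometric mean, the two-class AUC
#' (rank statistic of the \eqn{\delta_1-\delta_2} score; absent for K > 2)
#' and, when the indicator of truly informative variables is supplied, the
#' variable-selection counts: FDR (fraction of active variables that are
#' non-informative; defined as 0 when nothing is active) and FNR (fraction
#' of informative variables left inactive).
#'
#' @param model an `nsc_model`.
#' @param test_data an [nsc_data] test set whose class levels match the
#'   training levels; every training class must be present.
#' @param truth_informative optional logical vector of length p.
#' @param priors prior specification (default equal).
#' @param rng_seed optional seed for tie-breaking.
#' @return a one-row tibble: `pa_<level>` per class, `overall_pa`,
#'   `gmeans`, `auc`, `n_active`, `n_active_informative`,
#'   `n_active_noninformative`, `fdr`, `fnr`.
#' @export
nsc_evaluate <- function(model, test_data, truth_informative = NULL,
                         priors = "equal", rng_seed = NULL) {
  stopifnot(inherits(model, "nsc_model"), inherits(test_data, "nsc_data"))
  lv <- model$stats$class_levels
  if (!identical(test_data$class_levels, lv)) {
    missing <- setdiff(lv, test_data$class_levels)
    if (length(missing) > 0L) {
      stop(sprintf("class '%s' absent from the test set", missing[1L]))
    }
    stop("test-set class levels do not match the training levels")
  }
  pred <- nsc_classify(model, test_data$values, priors = priors,
                       rng_seed = rng_seed)
  y <- test_data$labels
  K <- length(lv)
  pa <- vapply(seq_len(K),
               function(k) mean(pred$class_index[y == k] == k), numeric(1))
  out <- tibble::tibble(!!!setNames(as.list(pa), paste0("pa_", lv)))
  out$overall_pa <- mean(pred$class_index == y)
  out$gmeans <- gmeans(pa)
  out$auc <- if (K == 2L) {
    auc_rank(two_class_score(model, test_data$values, priors = priors),
             positive = y == 2L)
  } else NA_real_
  na <- sum(model$active)
  out$n_active <- na
  if (!is.null(truth_informative)) {
    stopifnot(length(truth_informative) == model$stats$p)
    nai <- sum(model$active & truth_informative)
    nan <- na - nai
    out$n_active_informative <- nai
    out$n_active_noninformative <- nan
    out$fdr <- if (na == 0) 0 else nan / na
    out$fnr <- (sum(truth_informative) - nai) / sum(truth_informative)
  } else {
    out$n_active_informative <- NA_integer_
    out$n_active_noninformative <- NA_integer_
    out$fdr <- NA_real_
    out$fnr <- NA_real_
  }
  out
}
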