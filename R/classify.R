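#' Class prior specification
#'
#' The discriminant score carries a class prior correction
#' \eqn{-2\log(\pi_k)}. With high-dimensional data this term is dominated
#' by the distance part unless most variables are inactive, in which case
#' empirical priors bias assignment towards the majority class; the package
#' therefore defaults to equal priors \eqn{\pi_k = 1/K}.
#'
#' @param mode `"equal"` (default), `"empirical"` (training class
#'   fractions) or `"user"`.
#' @param values for `mode = "user"`: K positive values summing to 1.
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(mode = c("equal", "empirical", "user"),
                       values = NULL) {
  mode <- match.arg(mode)
  if (mode == "user") {
    if (is.null(values) || any(values <= 0) ||
        abs(sum(values) - 1) > 1e-8) {
      stop("user priors must be positive and sum to 1")
    }
  }
  structure(list(mode = mode, values = values), class = "prior_spec")
}

resolve_priors <- function(priors, stats) {
  if (is.character(priors)) priors <- prior_spec(priors)
  stopifnot(inherits(priors, "prior_spec"))
  switch(priors$mode,
    equal = rep(1 / stats$K, stats$K),
    empirical = stats$n_k / stats$n,
    user = {
      if (length(priors$values) != stats$K) {
        stop(sprintf("user priors have length %d, expected K=%d",
                     length(priors$values), stats$K))
      }
      priors$values
    }
  )
}

#' Discriminant scores of new samples
#'
#' The score of class `k` for a sample \eqn{x^*} is the standardized
#' squared distance to the shrunken centroid plus the prior correction:
#' \deqn{\delta_k(x^*) = \sum_j \frac{(x^*_j - \bar x'_{kj})^2}
#'   {(s_j + s_0)^2} - 2 \log \pi_k.}
#' The sample is assigned to the class with the smallest score.
#'
#' @param model an `nsc_model`.
#' @param x_new numeric matrix p x m (columns are samples) or a length-p
#'   vector for a single sample.
#' @param priors a [prior_spec] or one of `"equal"`, `"empirical"`,
#'   `"user"` (default `"equal"`).
#' @return m x K matrix of scores (rows samples, columns classes).
#' @export
discriminant_scores <- function(model, x_new, priors = "equal") {
  stopifnot(inherits(model, "nsc_model"))
  st <- model$stats
  if (is.vector(x_new)) x_new <- matrix(x_new, ncol = 1)
  if (nrow(x_new) != st$p) {
    stop(sprintf("`x_new` has %d variables, model expects %d",
                 nrow(x_new), st$p))
  }
  if (any(!is.finite(x_new))) stop("`x_new` must be finite")
  pk <- resolve_priors(priors, st)
  den <- st$pooled_sd + st$s0
  Xs <- x_new / den
  Cs <- model$centroids / den
  # ||xs - cs||^2 expanded; m x K
  delta <- outer(colSums(Xs^2), colSums(Cs^2), "+") - 2 * crossprod(Xs, Cs)
  delta <- sweep(delta, 2, 2 * log(pk), "-")
  dimnames(delta) <- list(colnames(x_new), st$class_levels)
  delta
}

# argmin per row with uniform random tie-breaking at relative tolerance
argmin_ties <- function(delta, tol = 1e-12) {
  m <- nrow(delta)
  cls <- integer(m)
  tied <- logical(m)
  for (i in seq_len(m)) {
    d <- delta[i, ]
    dmin <- min(d)
    ties <- which(d <= dmin + tol * max(1, abs(dmin)))
    if (length(ties) > 1L) {
      cls[i] <- ties[sample.int(length(ties), 1L)]
      tied[i] <- TRUE
    } else {
      cls[i] <- ties
    }
  }
  list(class = cls, tie_broken = tied)
}

#' Classify new samples
#'
#' Assigns each sample to the class minimizing the discriminant score;
#' exact (to relative tolerance `1e-12`) ties are broken uniformly at
#' random. Ties are the rule, not the exception, under complete shrinkage,
#' where every class centroid coincides with the overall centroid.
#'
#' @inheritParams discriminant_scores
#' @param rng_seed optional integer; when supplied, tie-breaking is run
#'   under this seed so repeated calls are identical.
#' @return a tibble with one row per sample: `sample_id`, `class`
#'   (external label), `class_index`, `tie_broken`, and one `delta_<level>`
#'   column per class.
#' @export
nsc_classify <- function(model, x_new, priors = "equal", rng_seed = NULL) {
  if (is.vector(x_new)) x_new <- matrix(x_new, ncol = 1)
  if (ncol(x_new) == 0L) {
    return(tibble::tibble(sample_id = character(), class = character(),
                          class_index = integer(), tie_broken = logical()))
  }
  delta <- discriminant_scores(model, x_new, priors)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  res <- argmin_ties(delta)
  lv <- model$stats$class_levels
  ids <- colnames(x_new)
  if (is.null(ids)) ids <- paste0("S", seq_len(ncol(x_new)))
  out <- tibble::tibble(
    sample_id = ids,
    class = lv[res$class],
    class_index = res$class,
    tie_broken = res$tie_broken
  )
  for (k in seq_along(lv)) out[[paste0("delta_", lv[k])]] <- delta[, k]
  out
}

#' Continuous two-class score for ROC analysis
#'
#' Returns \eqn{\delta_1 - \delta_2} for each sample: larger values mean
#' the sample looks more like class 2. Any strictly increasing transform
#' gives the same AUC, so the raw difference is used. Under complete
#' shrinkage all scores are zero and the AUC degenerates to 0.5.
#'
#' @inheritParams discriminant_scores
#' @return numeric vector of length m.
#' @export
two_class_score <- function(model, x_new, priors = "equal") {
  if (model$stats$K != 2L) {
    stop(sprintf("two_class_score requires K = 2 classes, got K = %d",
                 model$stats$K))
  }
  delta <- discriminant_scores(model, x_new, priors)
  unname(delta[, 1] - delta[, 2])
}
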