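#' Threshold grid from zero to complete shrinkage
#'
#' Evaluating the cross-validated criterion for every possible threshold is
#' infeasible, so tuning works on a fixed grid of `T` values spanning
#' `[0, lambda_max]`: 0 means no shrinkage (the DLDA-like limit), the upper
#' end collapses every centroid onto the overall centroid. Linear spacing
#' is the default; logarithmic spacing (0 prepended to a geometric sequence
#' from `lambda_max/1000`) concentrates candidate thresholds near zero,
#' which can help when many variables are informative.
#'
#' @inheritParams nsc_shrink
#' @param T number of grid points (>= 2, default 30).
#' @param spacing `"linear"` or `"log"`.
#' @return object of class `threshold_grid`: list with `values` (length
#'   `T`, increasing, first 0, last `lambda_max`), `spacing`, `lambda_max`.
#' @export
make_grid <- function(stats, method, T = 30L, spacing = c("linear", "log"),
                      weights = NULL, lambda_ratio = 1) {
  spacing <- match.arg(spacing)
  if (T < 2L) stop("`T` must be at least 2")
  lmax <- lambda_max(stats, method, weights = weights,
                     lambda_ratio = lambda_ratio)
  if (lmax == 0) {
    warning("lambda_max is 0 (no class separation); degenerate single-point grid")
    values <- 0
  } else if (spacing == "linear") {
    values <- seq(0, lmax, length.out = T)
  } else {
    values <- c(0, exp(seq(log(lmax * 1e-3), log(lmax), length.out = T - 1L)))
  }
  structure(list(values = values, spacing = spacing, lambda_max = lmax),
            class = "threshold_grid")
}

# stratified fold ids: shuffle within class, deal out cyclically so class
# counts per fold differ by at most one
stratified_folds <- function(labels, folds) {
  fold_id <- integer(length(labels))
  for (k in unique(labels)) {
    idx <- which(labels == k)
    idx <- idx[sample.int(length(idx))]
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

#' Cross-validated performance along a threshold grid
#'
#' Stratified K-fold cross-validation: within each fold the centroid
#' statistics, adaptive weights and shrinkage are re-estimated from the
#' training portion only, the held-out samples are classified at every grid
#' threshold, and the held-out predictions are pooled over folds before any
#' metric is computed (micro-averaging, matching the indicator-sum
#' estimator of the per-class predictive accuracies). Per threshold the
#' pooled overall error, per-class predictive accuracies, their geometric
#' mean (g-means) and the mean active-variable count are reported.
#'
#' @param data an [nsc_data] object.
#' @param method `"pam"`, `"alp"` or `"ahp"`.
#' @param grid a [make_grid()] result (built on the full training data).
#' @param folds number of CV folds (default 10); reduced with a warning if
#'   some class has fewer samples than folds. `folds = n` requests
#'   leave-one-out CV.
#' @param fold_seed integer seed driving fold assignment and random
#'   tie-breaking; fixed seed means fully reproducible CV.
#' @param priors prior specification, see [prior_spec()].
#' @param lambda_ratio AHP only, see [nsc_shrink()].
#' @return object of class `nsc_cv`: list with `table` (a tibble, one row
#'   per threshold: `threshold`, `error`, `gmeans`, `n_active`, `pa`
#'   list-column of per-class accuracies), `grid`, `folds`, `fold_seed`,
#'   `method`, `pooled` (n x T matrix of pooled CV class predictions).
#' @export
cross_validate <- function(data, method, grid, folds = 10L, fold_seed = 1L,
                           priors = "equal", lambda_ratio = 1) {
  stopifnot(inherits(data, "nsc_data"), inherits(grid, "threshold_grid"))
  method <- match.arg(method, c("pam", "alp", "ahp"))
  nk <- tabulate(data$labels, nbins = data$K)
  loocv <- folds == data$n
  if (!loocv && min(nk) < folds) {
    warning(sprintf("smallest class has %d samples; reducing folds from %d to %d",
                    min(nk), folds, min(nk)))
    folds <- min(nk)
  }
  if (folds < 2L) stop("need at least 2 folds")
  set.seed(fold_seed)
  fold_id <- if (loocv) seq_len(data$n) else
    stratified_folds(data$labels, folds)

  Tn <- length(grid$values)
  pred <- matrix(NA_integer_, data$n, Tn)
  n_act <- matrix(NA_real_, folds, Tn)
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    if (length(unique(data$labels[tr])) < data$K) {
      stop(sprintf("class absent from the training portion of fold %d", f))
    }
    st <- nsc_statistics(subset_samples(data, tr))
    w <- if (method == "pam") NULL else adaptive_weights(st)
    pk <- resolve_priors(priors, st)
    Xte <- data$values[, te, drop = FALSE]
    for (t in seq_len(Tn)) {
      model <- nsc_shrink(st, method, grid$values[t], weights = w,
                          lambda_ratio = lambda_ratio)
      n_act[f, t] <- sum(model$active)
      delta <- discriminant_scores(model, Xte, prior_spec("user", pk))
      pred[te, t] <- argmin_ties(delta)$class
    }
  }

  y <- data$labels
  pa <- vector("list", Tn)
  err <- gm <- numeric(Tn)
  for (t in seq_len(Tn)) {
    pa_t <- vapply(seq_len(data$K),
                   function(k) mean(pred[y == k, t] == k), numeric(1))
    names(pa_t) <- data$class_levels
    pa[[t]] <- pa_t
    err[t] <- mean(pred[, t] != y)
    gm[t] <- gmeans(pa_t)
  }
  tab <- tibble::tibble(threshold = grid$values, error = err, gmeans = gm,
                        n_active = colMeans(n_act), pa = pa)
  structure(list(table = tab, grid = grid, folds = folds,
                 fold_seed = fold_seed, method = method,
                 priors = priors, pooled = pred),
            class = "nsc_cv")
}

#' @export
print.nsc_cv <- function(x, ...) {
  cat(sprintf("<nsc_cv> method=%s, %d thresholds, %d folds\n",
              x$method, nrow(x$table), x$folds))
  print(x$table, n = 5)
  invisible(x)
}

#' Select the tuning threshold
#'
#' The original rule (`"min_error"`) takes the threshold minimizing the
#' pooled CV error; the GM rule (`"max_gmeans"`) maximizes the pooled CV
#' g-means, which weights every class equally and so resists the
#' majority-class bias of the error rule on imbalanced data. Ties are broken
#' towards the largest threshold (fewest active variables).
#'
#' @param cv an `nsc_cv` object.
#' @param criterion `"min_error"` or `"max_gmeans"`.
#' @return the selected threshold (a single number from the grid).
#' @export
select_threshold <- function(cv, criterion = c("min_error", "max_gmeans")) {
  criterion <- match.arg(criterion)
  tab <- cv$table
  score <- if (criterion == "min_error") -tab$error else tab$gmeans
  best <- which(score == max(score))
  tab$threshold[max(best)]
}

#' Fit a (GM-)NSC classifier end to end
#'
#' The full training pipeline: centroid statistics on the complete training
#' data, threshold grid to `lambda_max`, stratified cross-validation along
#' the grid, threshold selection by the chosen criterion, and a final
#' refit of the shrinkage on the complete data at the selected threshold.
#' `method` x `criterion` spans the six classifiers: PAM/ALP/AHP use
#' `criterion = "min_error"`, their GM variants use
#' `criterion = "max_gmeans"`.
#'
#' @inheritParams cross_validate
#' @param criterion threshold selection rule, see [select_threshold()].
#' @param T grid size (default 30).
#' @param spacing grid spacing, see [make_grid()].
#' @return object of class `nsc_fit`: list with `model` (the refit
#'   `nsc_model`), `cv` (`nsc_cv`), `lambda` (selected threshold),
#'   `criterion`, `priors` and `config` (all tuning settings and seeds).
#' @examples
#' set.seed(7)
#' x <- matrix(rnorm(50 * 24), 50, 24)
#' x[1:5, 13:24] <- x[1:5, 13:24] + 2
#' d <- nsc_data(x, rep(c("a", "b"), each = 12))
#' fit <- nsc_fit(d, method = "pam", criterion = "max_gmeans",
#'                T = 10, folds = 4, fold_seed = 1)
#' glance(fit)
#' @export
nsc_fit <- function(data, method = c("pam", "alp", "ahp"),
                    criterion = c("min_error", "max_gmeans"),
                    T = 30L, folds = 10L, spacing = "linear",
                    priors = "equal", fold_seed = 1L, lambda_ratio = 1) {
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  stats <- nsc_statistics(data)
  w <- if (method == "pam") NULL else adaptive_weights(stats)
  grid <- make_grid(stats, method, T = T, spacing = spacing, weights = w,
                    lambda_ratio = lambda_ratio)
  cv <- cross_validate(data, method, grid, folds = folds,
                       fold_seed = fold_seed, priors = priors,
                       lambda_ratio = lambda_ratio)
  lam <- select_threshold(cv, criterion)
  model <- nsc_shrink(stats, method, lam, weights = w,
                      lambda_ratio = lambda_ratio)
  config <- list(method = method, criterion = criterion, T = T,
                 folds = cv$folds, spacing = spacing,
                 priors = if (is.character(priors)) priors else priors$mode,
                 fold_seed = fold_seed, lambda_ratio = lambda_ratio)
  structure(list(model = model, cv = cv, lambda = lam,
                 criterion = criterion, priors = priors, config = config),
            class = "nsc_fit")
}

#' @export
print.nsc_fit <- function(x, ...) {
  lab <- classifier_label(x$config$method, x$criterion)
  cat(sprintf("<nsc_fit> %s: lambda*=%.4g, %d/%d active variables\n",
              lab, x$lambda, sum(x$model$active), x$model$stats$p))
  invisible(x)
}

classifier_label <- function(method, criterion) {
  base <- toupper(method)
  if (criterion == "max_gmeans") paste0("GM-", base) else base
}

#' Predict classes for new samples from a fitted classifier
#'
#' @param object an `nsc_fit`.
#' @param newdata p x m numeric matrix or an [nsc_data] object.
#' @param priors prior specification (defaults to the one used in tuning).
#' @param rng_seed optional seed for tie-breaking.
#' @param ... unused.
#' @return the prediction tibble of [nsc_classify()].
#' @export
predict.nsc_fit <- function(object, newdata, priors = NULL,
                            rng_seed = NULL, ...) {
  if (inherits(newdata, "nsc_data")) newdata <- newdata$values
  if (is.null(priors)) priors <- object$priors
  nsc_classify(object$model, newdata, priors = priors, rng_seed = rng_seed)
}

#' @describeIn nsc_fit per-threshold CV path as a tibble with one
#'   `cv_pa_<level>` column per class.
#' @param x an `nsc_fit` object (`tidy`/`glance`/`autoplot`).
#' @param ... unused.
#' @export
tidy.nsc_fit <- function(x, ...) {
  tab <- x$cv$table
  pa <- do.call(rbind, tab$pa)
  colnames(pa) <- paste0("cv_pa_", colnames(pa))
  out <- dplyr::select(tab, -"pa")
  names(out)[names(out) == "error"] <- "cv_error"
  names(out)[names(out) == "gmeans"] <- "cv_gmeans"
  dplyr::bind_cols(out, tibble::as_tibble(pa))
}

#' @describeIn nsc_fit one-row summary: classifier label, selected
#'   threshold, active-variable count, CV error and g-means at selection.
#' @export
glance.nsc_fit <- function(x, ...) {
  row <- which(x$cv$table$threshold == x$lambda)
  tibble::tibble(
    classifier = classifier_label(x$config$method, x$criterion),
    method = x$config$method,
    criterion = x$criterion,
    lambda = x$lambda,
    n_active = sum(x$model$active),
    cv_error = x$cv$table$error[row],
    cv_gmeans = x$cv$table$gmeans[row],
    folds = x$config$folds,
    T = nrow(x$cv$table)
  )
}

#' @describeIn nsc_fit CV error and g-means along the threshold grid, with
#'   the selected threshold marked.
#' @param object an `nsc_fit` (for `autoplot`).
#' @export
autoplot.nsc_fit <- function(object, ...) {
  tab <- tidy(object)
  long <- tidyr::pivot_longer(
    dplyr::select(tab, "threshold", "cv_error", "cv_gmeans"),
    cols = c("cv_error", "cv_gmeans"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$lambda, linetype = 2) +
    ggplot2::labs(x = "threshold", y = NULL,
                  title = sprintf("%s tuning path (lambda* = %.3g)",
                                  classifier_label(object$config$method,
                                                   object$criterion),
                                  object$lambda)) +
    ggplot2::theme_minimal()
}
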