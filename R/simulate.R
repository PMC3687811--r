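#' Monte-Carlo scenario for class-imbalance experiments
#'
#' Parameterizes one simulation experiment: samples are drawn from a
#' multivariate Gaussian with unit variances and block-exchangeable
#' correlation (pairwise correlation `rho` within consecutive blocks of
#' `block_size` variables, independence across blocks). Class `k` has mean
#' `mu_informative[k]` on the first `n_informative` variables and 0
#' elsewhere; informative variables are therefore contiguous and share
#' blocks. An independent test set is drawn from the same distribution,
#' balanced by default.
#'
#' @param p number of variables.
#' @param class_sizes integer vector of training samples per class.
#' @param mu_informative numeric vector, class means on the informative
#'   variables.
#' @param n_informative number of informative variables (first positions).
#' @param block_size variables per correlated block (default 100).
#' @param rho within-block pairwise correlation in `[0, 1)` (default 0.8).
#' @param test_size total test-set size.
#' @param test_balanced logical; balanced test classes (default) or the
#'   training mix.
#' @param n_replicates default replicate count for [run_experiment()].
#' @param base_seed integer; replicate `r` is generated under seed
#'   `base_seed + r`, so replicates are independent and individually
#'   re-runnable.
#' @param oversample logical; balance the training set by minority
#'   over-sampling before fitting (two-class only).
#' @return object of class `nsc_scenario`.
#' @export
nsc_scenario <- function(p, class_sizes, mu_informative,
                         n_informative = 100L, block_size = 100L,
                         rho = 0.8, test_size = 1000L,
                         test_balanced = TRUE, n_replicates = 500L,
                         base_seed = 1L, oversample = FALSE) {
  K <- length(class_sizes)
  if (K < 2L) stop("need at least two classes")
  if (length(mu_informative) != K) {
    stop("`mu_informative` must have one entry per class")
  }
  if (rho < 0 || rho >= 1) stop("`rho` must lie in [0, 1)")
  if (n_informative > p) stop("more informative variables than variables")
  structure(
    list(p = as.integer(p), class_sizes = as.integer(class_sizes),
         mu_informative = mu_informative,
         n_informative = as.integer(n_informative),
         block_size = as.integer(block_size), rho = rho,
         test_size = as.integer(test_size), test_balanced = test_balanced,
         n_replicates = as.integer(n_replicates),
         base_seed = as.integer(base_seed), oversample = oversample,
         K = K),
    class = "nsc_scenario"
  )
}

#' @export
print.nsc_scenario <- function(x, ...) {
  cat(sprintf(
    "<nsc_scenario> p=%d (blocks of %d, rho=%.2g), K=%d, n=(%s), mu=(%s) on %d variables, test=%d%s\n",
    x$p, x$block_size, x$rho, x$K,
    paste(x$class_sizes, collapse = ","),
    paste(x$mu_informative, collapse = ","),
    x$n_informative, x$test_size,
    if (x$oversample) ", oversampled" else ""))
  invisible(x)
}

#' Two-class study design
#'
#' Convenience constructor for the two-class design: `n` training samples
#' with majority fraction `k1` in class 1 (mean 0) and minority class 2
#' with mean `mu2` on 100 informative variables out of `p = 10000`
#' block-correlated variables, evaluated on a balanced test set of 1000.
#'
#' @param k1 proportion of class-1 (majority) training samples.
#' @param mu2 class-2 mean on the informative variables.
#' @param n training-set size.
#' @inheritParams nsc_scenario
#' @param ... passed to [nsc_scenario()].
#' @return an `nsc_scenario`.
#' @export
scenario_two_class <- function(k1 = 0.9, mu2 = 1, n = 100L, p = 10000L,
                               test_size = 1000L, base_seed = 1L, ...) {
  n1 <- as.integer(round(k1 * n))
  nsc_scenario(p = p, class_sizes = c(n1, n - n1),
               mu_informative = c(0, mu2), test_size = test_size,
               base_seed = base_seed, ...)
}

#' Three-class study design
#'
#' The nested-minority three-class design: classes 1 and 3 (100 training
#' samples each) have means +1 and -1 on the informative variables, the
#' minority class 2 (20 samples) sits between them at 0, with `p = 5000`
#' block-correlated variables and a balanced test set of 1500.
#'
#' @inheritParams scenario_two_class
#' @export
scenario_three_class <- function(p = 5000L, test_size = 1500L,
                                 base_seed = 1L, ...) {
  nsc_scenario(p = p, class_sizes = c(100L, 20L, 100L),
               mu_informative = c(1, 0, -1), test_size = test_size,
               base_seed = base_seed, ...)
}

# p x n draw with unit variances, exchangeable correlation rho inside
# consecutive blocks: sqrt(rho) * shared block normal + sqrt(1-rho) *
# independent normal is exact for this covariance
draw_block_gaussian <- function(p, n, block_size, rho) {
  Z <- matrix(rnorm(p * n), p, n)
  if (rho == 0) return(Z)
  nblocks <- ceiling(p / block_size)
  bi <- rep(seq_len(nblocks), each = block_size)[seq_len(p)]
  B <- matrix(rnorm(nblocks * n), nblocks, n)
  sqrt(1 - rho) * Z + sqrt(rho) * B[bi, , drop = FALSE]
}

split_test_sizes <- function(scenario) {
  K <- scenario$K
  if (scenario$test_balanced) {
    base <- scenario$test_size %/% K
    sizes <- rep(base, K)
    extra <- scenario$test_size - base * K
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  } else {
    sizes <- round(scenario$class_sizes / sum(scenario$class_sizes) *
                     scenario$test_size)
    sizes[K] <- scenario$test_size - sum(sizes[-K])
  }
  as.integer(sizes)
}

#' Generate one replicate of a simulation scenario
#'
#' Draws the training and test sets of replicate `replicate_index` under
#' seed `base_seed + replicate_index`; identical arguments always give
#' identical matrices.
#'
#' @param scenario an [nsc_scenario].
#' @param replicate_index positive integer.
#' @return list with `train` ([nsc_data]), `test` ([nsc_data]) and
#'   `truth_informative` (logical vector of length p).
#' @export
generate <- function(scenario, replicate_index = 1L) {
  stopifnot(inherits(scenario, "nsc_scenario"))
  set.seed(scenario$base_seed + as.integer(replicate_index))
  K <- scenario$K
  p <- scenario$p
  mu <- matrix(0, p, K)
  if (scenario$n_informative > 0) {
    for (k in seq_len(K)) {
      mu[seq_len(scenario$n_informative), k] <- scenario$mu_informative[k]
    }
  }
  make_set <- function(sizes, prefix) {
    n <- sum(sizes)
    labels <- rep(seq_len(K), sizes)
    X <- draw_block_gaussian(p, n, scenario$block_size, scenario$rho)
    X <- X + mu[, labels, drop = FALSE]
    dimnames(X) <- list(paste0("V", seq_len(p)),
                        paste0(prefix, seq_len(n)))
    nsc_data(X, as.character(labels))
  }
  train <- make_set(scenario$class_sizes, "tr")
  test <- make_set(split_test_sizes(scenario), "te")
  truth <- seq_len(p) <= scenario$n_informative
  list(train = train, test = test, truth_informative = truth)
}

#' Balance a two-class training set by minority over-sampling
#'
#' Appends `max(n1, n2) - min(n1, n2)` copies of uniformly drawn (with
#' replacement) minority-class samples, so both classes end up with
#' `max(n1, n2)` samples. Copies are bit-identical to their sources.
#' Already balanced data are returned unchanged.
#'
#' @param train a two-class [nsc_data].
#' @param seed optional integer seed for the draw.
#' @return an [nsc_data] with equal class sizes.
#' @export
oversample_minority <- function(train, seed = NULL) {
  stopifnot(inherits(train, "nsc_data"))
  if (train$K != 2L) stop("over-sampling is defined for two classes")
  nk <- tabulate(train$labels, nbins = 2L)
  if (nk[1] == nk[2]) return(train)
  if (!is.null(seed)) set.seed(seed)
  minority <- which.min(nk)
  n_add <- abs(nk[1] - nk[2])
  src <- which(train$labels == minority)
  pick <- src[sample.int(length(src), n_add, replace = TRUE)]
  values <- cbind(train$values, train$values[, pick, drop = FALSE])
  colnames(values) <- c(colnames(train$values),
                        paste0(colnames(train$values)[pick], ".os",
                               seq_len(n_add)))
  nsc_data(values, c(external_labels(train),
                     train$class_levels[train$labels[pick]]))
}

#' Run a Monte-Carlo classification experiment
#'
#' For each replicate: generate training and test data, optionally
#' over-sample the minority class, estimate the centroid statistics, run
#' one stratified CV along the threshold grid per method, derive the fit
#' for every selection criterion from that single CV path (the original
#' min-error rule and the GM rule share folds and grid, so this is exact),
#' refit on the full training data at each selected threshold and evaluate
#' on the independent test set. Failed replicates are recorded, not
#' silently dropped.
#'
#' @param scenario an [nsc_scenario].
#' @param methods character subset of `c("pam", "alp", "ahp")`.
#' @param criteria character subset of
#'   `c("min_error", "max_gmeans")`.
#' @param n_replicates number of replicates (defaults to the scenario's).
#' @param folds,T,spacing,priors,lambda_ratio tuning settings, see
#'   [nsc_fit()].
#' @param verbose print one line per replicate.
#' @return object of class `nsc_experiment`: list with `replicates` (a
#'   tibble, one row per replicate x method x criterion with the selected
#'   threshold and all evaluation metrics), `failures` (tibble), the
#'   `scenario` and the tuning `config`.
#' @export
run_experiment <- function(scenario, methods = "pam",
                           criteria = c("min_error", "max_gmeans"),
                           n_replicates = scenario$n_replicates,
                           folds = 10L, T = 30L, spacing = "linear",
                           priors = "equal", lambda_ratio = 1,
                           verbose = FALSE) {
  stopifnot(inherits(scenario, "nsc_scenario"))
  methods <- match.arg(methods, c("pam", "alp", "ahp"), several.ok = TRUE)
  criteria <- match.arg(criteria, c("min_error", "max_gmeans"),
                        several.ok = TRUE)
  rows <- list()
  fails <- list()
  for (r in seq_len(n_replicates)) {
    gen <- generate(scenario, r)
    train <- gen$train
    if (scenario$oversample) train <- oversample_minority(train)
    fold_seed <- scenario$base_seed + 100000L + r
    for (m in methods) {
      res <- tryCatch({
        stats <- nsc_statistics(train)
        w <- if (m == "pam") NULL else adaptive_weights(stats)
        grid <- make_grid(stats, m, T = T, spacing = spacing, weights = w,
                          lambda_ratio = lambda_ratio)
        cv <- cross_validate(train, m, grid, folds = folds,
                             fold_seed = fold_seed, priors = priors,
                             lambda_ratio = lambda_ratio)
        purrr::map_dfr(criteria, function(cr) {
          lam <- select_threshold(cv, cr)
          model <- nsc_shrink(stats, m, lam, weights = w,
                              lambda_ratio = lambda_ratio)
          ev <- nsc_evaluate(model, gen$test, gen$truth_informative,
                             priors = priors)
          dplyr::bind_cols(
            tibble::tibble(replicate = r, method = m, criterion = cr,
                           classifier = classifier_label(m, cr),
                           lambda = lam),
            ev)
        })
      }, error = function(e) e)
      if (inherits(res, "error")) {
        fails[[length(fails) + 1L]] <-
          tibble::tibble(replicate = r, method = m,
                         message = conditionMessage(res))
      } else {
        rows[[length(rows) + 1L]] <- res
      }
    }
    if (verbose) message(sprintf("replicate %d/%d done", r, n_replicates))
  }
  structure(
    list(replicates = dplyr::bind_rows(rows),
         failures = dplyr::bind_rows(fails),
         scenario = scenario,
         config = list(methods = methods, criteria = criteria,
                       n_replicates = n_replicates, folds = folds, T = T,
                       spacing = spacing,
                       priors = if (is.character(priors)) priors else priors$mode,
                       lambda_ratio = lambda_ratio)),
    class = "nsc_experiment"
  )
}

#' @export
print.nsc_experiment <- function(x, ...) {
  cat(sprintf("<nsc_experiment> %d replicates x {%s}, %d failures\n",
              x$config$n_replicates,
              paste(unique(x$replicates$classifier), collapse = ", "),
              nrow(x$failures)))
  print(experiment_table(x))
  invisible(x)
}

#' Aggregate an experiment into a study-style results table
#'
#' Means (and SDs) across replicates per classifier, in the layout of the
#' simulation tables: selected threshold, number of active informative
#' variables, number (and percentage) of active non-informative variables,
#' FDR, per-class predictive accuracies, g-means and (two-class) AUC.
#'
#' @param x an `nsc_experiment`.
#' @return a tibble with one row per classifier; each metric has a mean
#'   column and an `_sd` companion, plus `n_replicates` used.
#' @export
experiment_table <- function(x) {
  stopifnot(inherits(x, "nsc_experiment"))
  reps <- x$replicates
  metric_cols <- setdiff(names(reps),
                         c("replicate", "method", "criterion", "classifier"))
  n_noninf <- x$scenario$p - x$scenario$n_informative
  reps$pct_noninfo <- 100 * reps$n_active_noninformative / n_noninf
  metric_cols <- c(metric_cols, "pct_noninfo")
  dplyr::group_by(reps, .data$classifier, .data$method, .data$criterion) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      dplyr::across(dplyr::all_of(metric_cols),
                    list(mean = ~mean(.x), sd = ~sd(.x)),
                    .names = "{.col}_{.fn}"),
      .groups = "drop"
    ) |>
    dplyr::rename_with(~sub("_mean$", "", .x))
}

#' @describeIn run_experiment per-class predictive accuracies by
#'   classifier, one point per replicate with the mean highlighted.
#' @param object an `nsc_experiment` (for `autoplot`).
#' @param ... unused.
#' @export
autoplot.nsc_experiment <- function(object, ...) {
  pa_cols <- grep("^pa_", names(object$replicates), value = TRUE)
  long <- tidyr::pivot_longer(
    object$replicates[, c("classifier", pa_cols)],
    cols = dplyr::all_of(pa_cols),
    names_to = "class", values_to = "pa")
  long$class <- sub("^pa_", "", long$class)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$classifier, y = .data$pa,
                                     colour = .data$class)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 3,
                          position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "class-specific predictive accuracy", x = NULL) +
    ggplot2::theme_minimal()
}

#' Null-case probability of assignment to the minority class
#'
#' Illustrates the dimensionality side of the class-imbalance bias: under
#' the null (no class difference), with equal priors and no shrinkage, the
#' probability that a new sample is assigned to the minority class shrinks
#' as the number of variables grows, because the minority centroid is the
#' noisier estimate. Each value of `p` is assessed by Monte-Carlo
#' replicates of a null two-class scenario classified at threshold 0.
#'
#' @param p_values integer vector of dimensionalities to scan.
#' @param k1 majority-class training fraction.
#' @param n training-set size.
#' @param test_size test samples per replicate (balanced).
#' @param n_replicates replicates per `p`.
#' @param base_seed integer seed.
#' @param rho,block_size correlation structure, as in [nsc_scenario()].
#' @return tibble with columns `p` and `minority_fraction` (mean fraction
#'   of test samples assigned to the minority class).
#' @export
minority_assignment_curve <- function(p_values, k1 = 0.9, n = 100L,
                                      test_size = 200L, n_replicates = 10L,
                                      base_seed = 1L, rho = 0.8,
                                      block_size = 100L) {
  purrr::map_dfr(p_values, function(p) {
    sc <- scenario_two_class(k1 = k1, mu2 = 0, n = n, p = p,
                             test_size = test_size,
                             n_informative = 0L, rho = rho,
                             block_size = block_size,
                             base_seed = base_seed)
    frac <- vapply(seq_len(n_replicates), function(r) {
      gen <- generate(sc, r)
      stats <- nsc_statistics(gen$train)
      model <- pam_shrink(stats, 0)
      pred <- nsc_classify(model, gen$test$values, priors = "equal")
      mean(pred$class_index == 2L)
    }, numeric(1))
    tibble::tibble(p = p, minority_fraction = mean(frac))
  })
}
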