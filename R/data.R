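#' Labeled expression data container
#'
#' Bundles a variables-by-samples numeric matrix with per-sample class
#' labels. This is the universal input of the package: rows are variables
#' (genes, probes, features), columns are samples, following the microarray
#' convention. External labels may be arbitrary strings or factors; they are
#' mapped internally to the integers `1..K` in sorted order and the mapping
#' is kept in `class_levels` so that predictions can be reported on the
#' original scale.
#'
#' @param values numeric matrix, `p` variables x `n` samples. Row names (if
#'   present) are used as variable ids, column names as sample ids.
#' @param labels vector of length `n` with the class of each sample
#'   (character, factor or integer).
#' @param variable_ids optional character vector of `p` unique variable ids;
#'   defaults to row names or `V1..Vp`.
#' @param sample_ids optional character vector of `n` sample ids; defaults
#'   to column names or `S1..Sn`.
#'
#' @return An object of class `nsc_data`: a list with elements `values`
#'   (the matrix, with dimnames set), `labels` (integer classes `1..K`),
#'   `class_levels` (character vector of length `K`) and the dimensions
#'   `p`, `n`, `K`.
#'
#' @examples
#' x <- matrix(rnorm(20), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' d <- nsc_data(x, c("a", "a", "b", "b"))
#' d$K
#' @export
nsc_data <- function(values, labels, variable_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (variables x samples)")
  }
  p <- nrow(values)
  n <- ncol(values)
  if (p < 1L) stop("need at least one variable")
  if (length(labels) != n) {
    stop(sprintf("`labels` has length %d but there are %d samples",
                 length(labels), n))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` contains missing or non-finite entries")
  }
  if (anyNA(labels)) stop("`labels` contains missing values")

  if (is.null(variable_ids)) variable_ids <- rownames(values)
  if (is.null(variable_ids)) variable_ids <- paste0("V", seq_len(p))
  if (anyDuplicated(variable_ids)) {
    dup <- variable_ids[duplicated(variable_ids)][1L]
    stop(sprintf("duplicate variable id: '%s'", dup))
  }
  if (is.null(sample_ids)) sample_ids <- colnames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))

  if (is.factor(labels)) labels <- as.character(labels)
  class_levels <- sort(unique(as.character(labels)))
  K <- length(class_levels)
  if (K < 2L) stop("need at least two classes")
  if (n < K) stop("fewer samples than classes")
  y <- match(as.character(labels), class_levels)

  dimnames(values) <- list(variable_ids, sample_ids)
  structure(
    list(values = values, labels = y, class_levels = class_levels,
         p = p, n = n, K = K),
    class = "nsc_data"
  )
}

#' @export
print.nsc_data <- function(x, ...) {
  cat(sprintf("<nsc_data> %d variables x %d samples, %d classes\n",
              x$p, x$n, x$K))
  tab <- table(factor(x$class_levels[x$labels], levels = x$class_levels))
  cat("  class sizes:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-class sample counts
#' @param data an [nsc_data] object.
#' @return integer vector of length `K`, named by class level.
#' @export
class_counts <- function(data) {
  stopifnot(inherits(data, "nsc_data"))
  nk <- tabulate(data$labels, nbins = data$K)
  names(nk) <- data$class_levels
  nk
}

# subset samples by index, keeping the class-level mapping intact
subset_samples <- function(data, idx) {
  out <- data
  out$values <- data$values[, idx, drop = FALSE]
  out$labels <- data$labels[idx]
  out$n <- length(idx)
  out
}

#' External (string) labels of an nsc_data object
#' @param data an [nsc_data] object.
#' @return character vector of length `n`.
#' @export
external_labels <- function(data) {
  stopifnot(inherits(data, "nsc_data"))
  data$class_levels[data$labels]
}
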