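sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (lengths(regmatches(first, gregexpr("\t", first))) >=
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

#' Read a delimited expression matrix (and optional labels)
#'
#' The matrix file is delimited text with variables in rows and samples in
#' columns: a header row of sample ids and a first column of variable ids.
#' Tab and comma delimiters are auto-detected. The labels file maps sample
#' id to class, with header columns `sample_id` and `class`; sample order
#' is taken from the matrix header and labels are joined by id.
#'
#' @param path matrix file.
#' @param labels_path optional labels file; when supplied an [nsc_data] is
#'   returned, otherwise the bare numeric matrix.
#' @param delim field delimiter; default auto-detects tab vs comma.
#' @param transpose set `TRUE` when the file stores samples in rows.
#' @return an [nsc_data] (with labels) or a p x n numeric matrix.
#' @export
read_expression <- function(path, labels_path = NULL, delim = NULL,
                            transpose = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  if (is.null(delim)) delim <- sniff_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2L) stop("matrix file needs an id column plus data columns")
  ids <- as.character(df[[1L]])
  num <- df[, -1L, drop = FALSE]
  for (j in seq_along(num)) {
    if (!is.numeric(num[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(num[[j]]))))[1L]
      stop(sprintf("non-numeric value in column '%s', row %d of '%s'",
                   names(num)[j], bad, path))
    }
  }
  values <- as.matrix(num)
  rownames(values) <- ids
  if (transpose) values <- t(values)
  if (anyDuplicated(rownames(values))) {
    stop(sprintf("duplicate variable id: '%s'",
                 rownames(values)[duplicated(rownames(values))][1L]))
  }
  if (is.null(labels_path)) return(values)
  labels <- read_labels(labels_path)
  idx <- match(colnames(values), labels$sample_id)
  if (anyNA(idx)) {
    stop(sprintf("no label for sample '%s'",
                 colnames(values)[is.na(idx)][1L]))
  }
  nsc_data(values, labels$class[idx])
}

#' Read a sample-to-class labels file
#'
#' @param path delimited file with header columns `sample_id` and `class`.
#' @param delim delimiter, auto-detected by default.
#' @return tibble with columns `sample_id`, `class` (both character).
#' @export
read_labels <- function(path, delim = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  if (is.null(delim)) delim <- sniff_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"")
  if (!all(c("sample_id", "class") %in% names(df))) {
    stop("labels file must have header columns 'sample_id' and 'class'")
  }
  tibble::tibble(sample_id = as.character(df$sample_id),
                 class = as.character(df$class))
}

#' Write an expression matrix (and optionally labels) as delimited text
#'
#' @param data an [nsc_data] or a p x n numeric matrix with dimnames.
#' @param path output matrix file.
#' @param labels_path optional output labels file (only for [nsc_data]).
#' @param delim field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_expression <- function(data, path, labels_path = NULL, delim = "\t") {
  values <- if (inherits(data, "nsc_data")) data$values else data
  df <- data.frame(variable_id = rownames(values), values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = delim, quote = FALSE,
                     row.names = FALSE)
  if (!is.null(labels_path)) {
    if (!inherits(data, "nsc_data")) stop("labels require an nsc_data input")
    utils::write.table(
      data.frame(sample_id = colnames(values),
                 class = external_labels(data)),
      labels_path, sep = delim, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# doubles are persisted as C99 hex-float strings: exact binary round trip,
# still plain text
num_to_hex <- function(x) sprintf("%a", as.numeric(x))
hex_to_num <- function(x) as.numeric(x)

mat_to_payload <- function(m) {
  list(values = num_to_hex(m), nrow = nrow(m), ncol = ncol(m))
}

mat_from_payload <- function(x, dn = NULL) {
  m <- matrix(hex_to_num(x$values), x$nrow, x$ncol)
  dimnames(m) <- dn
  m
}

MODEL_FORMAT <- "gmnsc-model"
MODEL_VERSION <- 1L

md5_string <- function(s) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(s, tmp, sep = "")
  unname(tools::md5sum(tmp))
}

#' Persist a fitted classifier as a versioned text container
#'
#' Writes the complete fitted state - shrunken model, centroid statistics,
#' tuning path and run configuration - as a single self-describing text
#' file: a header line carrying the format name, version and an md5
#' checksum of the body, followed by a JSON payload serialized at full
#' floating-point precision so that predictions from a reloaded model are
#' bit-identical.
#'
#' @param fit an `nsc_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "nsc_fit"))
  st <- fit$model$stats
  payload <- list(
    method = fit$model$method,
    threshold = fit$model$threshold,
    lambda = fit$lambda,
    criterion = fit$criterion,
    config = fit$config,
    class_levels = st$class_levels,
    variable_ids = st$variable_ids,
    n = st$n, K = st$K, p = st$p,
    n_k = st$n_k, m = num_to_hex(st$m), s0 = num_to_hex(st$s0),
    overall = num_to_hex(st$overall), pooled_sd = num_to_hex(st$pooled_sd),
    centroids = mat_to_payload(st$centroids),
    d = mat_to_payload(st$d),
    d_hat = mat_to_payload(fit$model$d_hat),
    shrunken = mat_to_payload(fit$model$centroids),
    active = fit$model$active,
    tuning = list(
      grid = fit$cv$grid$values,
      spacing = fit$cv$grid$spacing,
      lambda_max = fit$cv$grid$lambda_max,
      folds = fit$cv$folds,
      fold_seed = fit$cv$fold_seed,
      table = as.data.frame(tidy(fit))
    )
  )
  body <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                           null = "null")
  header <- sprintf("%s/%d md5=%s", MODEL_FORMAT, MODEL_VERSION,
                    md5_string(as.character(body)))
  writeLines(c(header, as.character(body)), path)
  invisible(path)
}

#' Load a classifier saved by [save_model()]
#'
#' Verifies the format, version and checksum, then reconstructs the
#' `nsc_fit` (without the training matrix, which is not needed for
#' prediction or evaluation).
#'
#' @param path file written by [save_model()].
#' @return an `nsc_fit`.
#' @export
load_model <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("not a model container: file too short")
  hdr <- strsplit(lines[1L], " ", fixed = TRUE)[[1L]]
  fmt <- strsplit(hdr[1L], "/", fixed = TRUE)[[1L]]
  if (fmt[1L] != MODEL_FORMAT) {
    stop(sprintf("not a %s container: '%s'", MODEL_FORMAT, hdr[1L]))
  }
  if (as.integer(fmt[2L]) != MODEL_VERSION) {
    stop(sprintf("unsupported model container version %s (supported: %d)",
                 fmt[2L], MODEL_VERSION))
  }
  body <- paste(lines[-1L], collapse = "\n")
  want <- sub("^md5=", "", hdr[2L])
  got <- md5_string(body)
  if (!identical(want, got)) {
    stop("model container checksum mismatch: file corrupted or tampered")
  }
  pl <- jsonlite::fromJSON(body, simplifyVector = TRUE)

  dn <- list(pl$variable_ids, pl$class_levels)
  st <- structure(
    list(centroids = mat_from_payload(pl$centroids, dn),
         overall = setNames(hex_to_num(pl$overall), pl$variable_ids),
         pooled_sd = setNames(hex_to_num(pl$pooled_sd), pl$variable_ids),
         s0 = hex_to_num(pl$s0), m = hex_to_num(pl$m),
         d = mat_from_payload(pl$d, dn), n_k = pl$n_k, n = pl$n,
         K = pl$K, p = pl$p, class_levels = pl$class_levels,
         variable_ids = pl$variable_ids),
    class = "nsc_statistics")
  model <- structure(
    list(method = pl$method, threshold = as.list(pl$threshold),
         d_hat = mat_from_payload(pl$d_hat, dn),
         centroids = mat_from_payload(pl$shrunken, dn),
         active = pl$active, weights = NULL, stats = st),
    class = "nsc_model")
  tab <- tibble::as_tibble(pl$tuning$table)
  pa_cols <- grep("^cv_pa_", names(tab), value = TRUE)
  cv_table <- tibble::tibble(
    threshold = tab$threshold, error = tab$cv_error,
    gmeans = tab$cv_gmeans, n_active = tab$n_active,
    pa = lapply(seq_len(nrow(tab)), function(i) {
      setNames(as.numeric(tab[i, pa_cols]), sub("^cv_pa_", "", pa_cols))
    }))
  cv <- structure(
    list(table = cv_table,
         grid = structure(list(values = pl$tuning$grid,
                               spacing = pl$tuning$spacing,
                               lambda_max = pl$tuning$lambda_max),
                          class = "threshold_grid"),
         folds = pl$tuning$folds, fold_seed = pl$tuning$fold_seed,
         method = pl$method, priors = pl$config$priors, pooled = NULL),
    class = "nsc_cv")
  structure(
    list(model = model, cv = cv, lambda = pl$lambda,
         criterion = pl$criterion, priors = pl$config$priors,
         config = pl$config),
    class = "nsc_fit")
}

#' Write / read a scenario as a flat key=value config file
#'
#' @param scenario an [nsc_scenario].
#' @param path config file path.
#' @return `path` invisibly ([write_scenario_config()]); an
#'   [nsc_scenario] ([read_scenario_config()]).
#' @export
write_scenario_config <- function(scenario, path) {
  stopifnot(inherits(scenario, "nsc_scenario"))
  fields <- scenario[setdiff(names(scenario), "K")]
  lines <- vapply(names(fields), function(nm) {
    sprintf("%s=%s", nm, paste(fields[[nm]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1))
  get <- function(key, as = as.numeric, default = NULL) {
    if (!key %in% keys) {
      if (is.null(default)) stop(sprintf("missing config key '%s'", key))
      return(default)
    }
    as(strsplit(vals[match(key, keys)], ",", fixed = TRUE)[[1L]])
  }
  nsc_scenario(
    p = get("p"),
    class_sizes = get("class_sizes"),
    mu_informative = get("mu_informative"),
    n_informative = get("n_informative", default = 100),
    block_size = get("block_size", default = 100),
    rho = get("rho", default = 0.8),
    test_size = get("test_size", default = 1000),
    test_balanced = get("test_balanced", as = as.logical, default = TRUE),
    n_replicates = get("n_replicates", default = 500),
    base_seed = get("base_seed", default = 1),
    oversample = get("oversample", as = as.logical, default = FALSE)
  )
}

#' Write an aggregated experiment table as TSV
#'
#' Emits the [experiment_table()] layout preceded by `#`-prefixed header
#' lines embedding the scenario and tuning configuration, so every results
#' file records the run that produced it.
#'
#' @param x an `nsc_experiment`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_experiment_tsv <- function(x, path) {
  stopifnot(inherits(x, "nsc_experiment"))
  tab <- experiment_table(x)
  sc <- x$scenario[setdiff(names(x$scenario), "K")]
  hdr <- c(
    vapply(names(sc), function(nm) {
      sprintf("# scenario.%s=%s", nm, paste(sc[[nm]], collapse = ","))
    }, character(1)),
    vapply(names(x$config), function(nm) {
      sprintf("# config.%s=%s", nm, paste(x$config[[nm]], collapse = ","))
    }, character(1))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(tab), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
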