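## Readers and writers. Count files are samples x features: the header row
## holds feature ids and the first column holds sample ids. MatrixMarket
## input uses sidecar label files ("<stem>.rows.txt", "<stem>.cols.txt").

#' Construct a validated count matrix
#'
#' @param values n x d matrix of nonnegative integers.
#' @param sample_ids unique row labels (default `s1..sn`).
#' @param feature_ids unique column labels (default `f1..fd`).
#' @param offsets optional log offsets (scalar, per-sample, or n x d).
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(values, sample_ids = NULL, feature_ids = NULL,
                         offsets = NULL) {
  values <- as.matrix(values)
  if (any(is.na(values))) stop("count matrix contains missing values")
  check_counts(values, "values")
  n <- nrow(values); d <- ncol(values)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(d))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids")
  stopifnot(length(sample_ids) == n, length(feature_ids) == d)
  storage.mode(values) <- "integer"
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(values = values,
                 sample_ids = as.character(sample_ids),
                 feature_ids = as.character(feature_ids),
                 offsets = expand_offsets(offsets, n, d)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
         stop("cannot guess format from extension '.", ext,
              "'; pass format explicitly"))
}

#' Read a count matrix from TSV, CSV, or MatrixMarket
#'
#' Delimited input must carry a header row of feature ids and a first column
#' of sample ids. Entries must be nonnegative integers; fractional entries
#' are rejected rather than rounded. MatrixMarket (coordinate) input reads
#' labels from `<stem>.rows.txt` / `<stem>.cols.txt` next to the matrix file
#' when present.
#'
#' @param path input file.
#' @param format `"tsv"`, `"csv"`, `"mtx"`, or `"auto"` (by extension).
#' @param transpose if `TRUE`, the file is features x samples and is
#'   transposed on read.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                        transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guess_format(path)
  if (format == "mtx") {
    if (!requireNamespace("Matrix", quietly = TRUE)) {
      stop("reading MatrixMarket files requires the Matrix package")
    }
    M <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rf <- paste0(stem, ".rows.txt"); cf <- paste0(stem, ".cols.txt")
    rn <- if (file.exists(rf)) readLines(rf) else NULL
    cn <- if (file.exists(cf)) readLines(cf) else NULL
    if (transpose) { M <- t(M); tmp <- rn; rn <- cn; cn <- tmp }
    return(count_matrix(M, sample_ids = rn, feature_ids = cn))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("malformed header: expected sample-id column plus features")
  ids <- as.character(df[[1L]])
  M <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(M)) stop("non-numeric entries in count matrix")
  if (transpose) {
    M <- t(M); cn <- ids; ids <- colnames(df)[-1L]
    return(count_matrix(M, sample_ids = ids, feature_ids = cn))
  }
  count_matrix(M, sample_ids = ids, feature_ids = colnames(df)[-1L])
}

#' Write a count matrix to TSV or CSV
#'
#' @param x a [count_matrix()] or plain matrix.
#' @param path output file.
#' @param format `"tsv"` or `"csv"`.
#' @export
write_counts <- function(x, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  if (inherits(x, "count_matrix")) x <- x$values
  df <- data.frame(sample_id = rownames(x) %||% paste0("s", seq_len(nrow(x))),
                   x, check.names = FALSE)
  write.table(df, path, sep = if (format == "tsv") "\t" else ",",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

results_payload <- function(fit, seed = NULL) {
  base <- list(schema_version = "1.0",
               package = "plncount",
               software_version = as.character(packageVersion("plncount")),
               seed = seed %||% NA_integer_)
  body <- if (inherits(fit, "univariate_fit")) {
    list(type = "univariate_fit", family = fit$family,
         params = unclass(fit$params), moments = fit$fitted_moments,
         loglik = fit$loglik, converged = fit$converged)
  } else if (inherits(fit, "mpln_fit")) {
    list(type = "mpln_fit", mu = fit$params$mu, Sigma = fit$params$Sigma,
         moments = mpln_moments(fit$params), elbo = fit$elbo,
         converged = fit$converged)
  } else if (inherits(fit, "mpln_mixture")) {
    list(type = "mpln_mixture", G = fit$G, pi = fit$pi,
         components = lapply(fit$components, unclass),
         bic = fit$bic, labels = fit$labels, converged = fit$converged,
         seed = fit$seed)
  } else if (inherits(fit, "mpln_model_selection")) {
    sel <- fit$bic_table[order(fit$bic_table$G), ]
    list(type = "mpln_model_selection", chosen_G = fit$chosen_G,
         bic_table = sel, best = results_payload(fit$best)$body)
  } else stop("unsupported object for write_results: ", class(fit)[1L])
  list(base = base, body = body)
}

#' Write a fit or model selection to schema-versioned JSON
#'
#' @param fit a `univariate_fit`, `mpln_fit`, `mpln_mixture`, or
#'   `mpln_model_selection` object.
#' @param path output JSON file.
#' @param seed seed recorded in the document.
#' @return the path, invisibly.
#' @export
write_results <- function(fit, path, seed = NULL) {
  p <- results_payload(fit, seed)
  jsonlite::write_json(c(p$base, p$body), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Read a results JSON document
#'
#' Validates the presence of the schema, type, and seed fields.
#'
#' @param path JSON file written by [write_results()].
#' @return named list.
#' @export
read_results <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("schema_version", "type", "seed")) {
    if (is.null(doc[[field]])) stop("results document is missing field '", field, "'")
  }
  doc
}
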