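# Readers and writers for the TSV/CSV interchange formats: count tables
# (samples x taxa, QIIME-style transposed tables via a flag), compositions,
# fitted hyperparameters and ELBO traces.

sep_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a count table from TSV/CSV
#'
#' Expects a header row of taxon ids and a first column of sample ids
#' (samples x taxa). QIIME-style tables (taxa in rows) are accepted with
#' `orientation = "taxa-by-samples"`, in which case the file is transposed
#' after reading. Cells must be nonnegative integers with no missing values;
#' zero-depth samples are rejected.
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (`.csv` is comma-separated, anything else tab-separated).
#' @param orientation `"samples-by-taxa"` (default) or `"taxa-by-samples"`.
#' @return A [count_table()].
#' @export
read_count_table <- function(path,
                             orientation = c("samples-by-taxa",
                                             "taxa-by-samples")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep_for(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2) stop("count file needs an id column plus data columns",
                         call. = FALSE)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    stop("non-numeric cell(s) in ", path,
         "; counts must be nonnegative integers", call. = FALSE)
  }
  if (orientation == "taxa-by-samples") {
    mat <- t(mat)
    count_table(mat, sample_ids = rownames(mat), taxon_ids = ids)
  } else {
    count_table(mat, sample_ids = ids, taxon_ids = colnames(mat))
  }
}

#' Write a count table to TSV/CSV
#'
#' @param table A [count_table()].
#' @param path Output path (delimiter inferred from extension).
#' @return Invisibly, `path`.
#' @export
write_count_table <- function(table, path) {
  assert_count_table(table)
  df <- data.frame(sample_id = table$sample_ids, table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", table$taxon_ids)
  utils::write.table(df, path, sep = sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a composition matrix to TSV/CSV at full precision
#'
#' Values are written with 15 significant digits so the matrix round-trips
#' through [read_composition()] within 1e-10.
#'
#' @param comp A [composition()] matrix (at least one sample).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_composition <- function(comp, path) {
  comp <- as.matrix(comp)
  if (nrow(comp) < 1 || ncol(comp) < 1) {
    stop("refusing to write an empty composition", call. = FALSE)
  }
  vals <- unclass_matrix(comp)
  df <- data.frame(sample_id = rownames(vals) %||% paste0("S", seq_len(nrow(vals))),
                   vals, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id",
                    colnames(vals) %||% paste0("T", seq_len(ncol(vals))))
  utils::write.table(df, path, sep = sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a composition matrix written by [write_composition()]
#'
#' @param path File path.
#' @return A [composition()] matrix.
#' @export
read_composition <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep_for(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  mat <- as.matrix(df[, -1, drop = FALSE])
  composition(mat, sample_ids = as.character(df[[1]]),
              taxon_ids = colnames(mat))
}

#' Write fitted hyperparameters to TSV
#'
#' One row per taxon with columns `taxon`, `pi`, `alpha0`, `alpha1`.
#'
#' @param hyper A [hyperparams()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hyperparams <- function(hyper, path) {
  assert_hyperparams(hyper)
  df <- data.frame(taxon = hyper$taxon_ids, pi = hyper$pi,
                   alpha0 = hyper$alpha0, alpha1 = hyper$alpha1,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read hyperparameters written by [write_hyperparams()]
#'
#' @param path File path.
#' @return A [hyperparams()] object.
#' @export
read_hyperparams <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep_for(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  hyperparams(df$pi, df$alpha0, df$alpha1, taxon_ids = df$taxon)
}

write_elbo_trace <- function(fit, path) {
  df <- data.frame(iteration = seq_along(fit$elbo_trace),
                   elbo = fit$elbo_trace)
  utils::write.table(df, path, sep = sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
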