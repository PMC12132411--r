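#' Construct a validated count table
#'
#' A count table holds the observed read counts of `m` taxa in `n` samples,
#' together with the per-sample sequencing depths (row totals). It is the
#' primary input of [bmdd_fit()].
#'
#' @param counts An `n x m` matrix of nonnegative integer read counts
#'   (samples in rows, taxa in columns). Numeric storage is accepted as long
#'   as every value is integer-valued.
#' @param sample_ids Optional character vector of `n` unique sample labels.
#'   Defaults to existing rownames or `"S1"..."Sn"`.
#' @param taxon_ids Optional character vector of `m` unique taxon labels.
#'   Defaults to existing colnames or `"T1"..."Tm"`.
#'
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer-valued matrix with dimnames), `sample_ids`, `taxon_ids` and
#'   `depths` (the row totals).
#'
#' @details Every sample must have positive depth: a sample with zero total
#'   reads carries no information about its composition and is rejected.
#'   All-zero taxa are allowed (their imputed abundance is prior-driven).
#'
#' @examples
#' ct <- count_table(matrix(c(0L, 3L, 5L, 2L), 2, 2))
#' ct$depths
#' @export
count_table <- function(counts, sample_ids = NULL, taxon_ids = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("'counts' must be a numeric matrix of read counts", call. = FALSE)
  }
  if (anyNA(counts)) {
    bad <- which(is.na(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("NA count at sample row %d, taxon column %d; counts must be complete",
                 bad[1], bad[2]), call. = FALSE)
  }
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample row %d, taxon column %d",
                 bad[1], bad[2]), call. = FALSE)
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at sample row %d, taxon column %d",
                 bad[1], bad[2]), call. = FALSE)
  }
  counts <- round(counts)
  n <- nrow(counts)
  m <- ncol(counts)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(counts)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  }
  if (is.null(taxon_ids)) {
    taxon_ids <- colnames(counts)
    if (is.null(taxon_ids)) taxon_ids <- paste0("T", seq_len(m))
  }
  sample_ids <- as.character(sample_ids)
  taxon_ids <- as.character(taxon_ids)
  if (length(sample_ids) != n) stop("length(sample_ids) != nrow(counts)", call. = FALSE)
  if (length(taxon_ids) != m) stop("length(taxon_ids) != ncol(counts)", call. = FALSE)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ", paste(unique(sample_ids[duplicated(sample_ids)]),
                                         collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(taxon_ids)) {
    stop("duplicate taxon ids: ", paste(unique(taxon_ids[duplicated(taxon_ids)]),
                                        collapse = ", "), call. = FALSE)
  }
  depths <- rowSums(counts)
  if (any(depths <= 0)) {
    stop("zero-depth sample(s): ", paste(sample_ids[depths <= 0], collapse = ", "),
         "; samples with no reads must be removed before fitting", call. = FALSE)
  }
  dimnames(counts) <- list(sample_ids, taxon_ids)
  structure(
    list(counts = counts, sample_ids = sample_ids, taxon_ids = taxon_ids,
         depths = depths),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa\n", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  depths: %s .. %s (median %s)\n",
              format(min(x$depths)), format(max(x$depths)),
              format(stats::median(x$depths))))
  cat(sprintf("  zero fraction: %.3f\n", mean(x$counts == 0)))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

is_count_table <- function(x) inherits(x, "count_table")

assert_count_table <- function(x) {
  if (!is_count_table(x)) stop("expected a 'count_table' object; see count_table()",
                               call. = FALSE)
  invisible(x)
}

#' Construct a validated composition matrix
#'
#' A composition is a row-stochastic matrix of relative abundances: one row
#' per sample, entries nonnegative, each row summing to 1.
#'
#' @param values An `n x m` numeric matrix of relative abundances.
#' @param sample_ids,taxon_ids Optional axis labels (defaults as in
#'   [count_table()]).
#' @return A numeric matrix of class `composition` with dimnames set.
#' @examples
#' composition(matrix(c(0.2, 0.5, 0.8, 0.5), 2, 2))
#' @export
composition <- function(values, sample_ids = NULL, taxon_ids = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 1 || ncol(values) < 1) {
    stop("a composition needs at least one sample and one taxon", call. = FALSE)
  }
  if (anyNA(values) || any(values < 0)) {
    stop("composition entries must be nonnegative and non-missing", call. = FALSE)
  }
  rs <- rowSums(values)
  if (any(abs(rs - 1) > 1e-8)) {
    stop("composition rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  }
  if (is.null(taxon_ids)) {
    taxon_ids <- colnames(values)
    if (is.null(taxon_ids)) taxon_ids <- paste0("T", seq_len(ncol(values)))
  }
  dimnames(values) <- list(as.character(sample_ids), as.character(taxon_ids))
  class(values) <- c("composition", class(values))
  values
}

# normalize rows of a nonnegative matrix to compositions
row_normalize <- function(x) {
  rs <- rowSums(x)
  if (any(rs <= 0)) stop("cannot normalize a row with nonpositive sum", call. = FALSE)
  sweep(x, 1, rs, "/")
}
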