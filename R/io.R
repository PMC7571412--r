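#' Count matrix I/O
#'
#' A count matrix is the pipeline's central exchange format: an integer
#' matrix with samples as rows (rownames = sample IDs) and barcodes as
#' columns (colnames = barcode IDs). On disk it is a TSV whose first
#' column is `sample_id` and whose remaining columns are barcode IDs.
#'
#' @param counts integer matrix, samples x barcodes, non-negative
#' @param path file path for the TSV
#' @return `write_count_matrix` returns `path` invisibly;
#'   `read_count_matrix` returns the integer matrix.
#' @export
write_count_matrix <- function(counts, path) {
  counts <- as_count_matrix(counts)
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  .check_tsv_rectangular(path)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 1L || names(df)[1L] != "sample_id")
    stop("count matrix TSV must have 'sample_id' as its first column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (is.null(dim(m)) || !is.numeric(m))
    stop("count matrix TSV has non-numeric count columns")
  rownames(m) <- df$sample_id
  as_count_matrix(m)
}

# Validate and coerce to the canonical count-matrix form.
as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must have sample rownames and barcode colnames")
  storage.mode(counts) <- "integer"
  counts
}

#' Per-sample totals of a count matrix
#'
#' @param counts count matrix (samples x barcodes)
#' @return named numeric vector of row sums T_j
#' @export
sample_totals <- function(counts) {
  rowSums(as_count_matrix(counts))
}

# Error with the first offending line number if a TSV is ragged.
.check_tsv_rectangular <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) == 0L) stop("empty TSV: ", path)
  bad <- which(nf != nf[1L])
  if (length(bad))
    stop(sprintf("malformed TSV %s: line %d has %d fields, expected %d",
                 path, bad[1L], nf[bad[1L]], nf[1L]))
  invisible(TRUE)
}

#' Sample sheet I/O
#'
#' A sample sheet maps each sequencing sample to its forward/reverse index
#' pair, its expected barcode set, and its experimental metadata. The TSV
#' columns are: sample_id, fwd_index, rev_index, expected_barcodes
#' (semicolon-separated barcode IDs, order preserved: the first barcode of
#' a two-barcode population is the focal one), pool_id, treatment_id,
#' timepoint, replicate.
#'
#' @param sheet data.frame in the in-memory representation (column
#'   `expected_barcodes` is a list of character vectors)
#' @param path TSV path
#' @export
write_sample_sheet <- function(sheet, path) {
  out <- sheet
  out$expected_barcodes <- vapply(sheet$expected_barcodes,
                                  paste, character(1), collapse = ";")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  .check_tsv_rectangular(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "fwd_index", "rev_index", "expected_barcodes",
              "pool_id", "treatment_id", "timepoint", "replicate")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("sample sheet missing column(s): ", paste(missing, collapse = ", "))
  df$expected_barcodes <- strsplit(as.character(df$expected_barcodes), ";",
                                   fixed = TRUE)
  df
}

#' Barcode library I/O (TSV: barcode_id, sequence)
#'
#' @param library data.frame with columns barcode_id, sequence
#' @param path TSV path
#' @export
write_barcode_library <- function(library, path) {
  utils::write.table(library[, c("barcode_id", "sequence")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_barcode_library
#' @export
read_barcode_library <- function(path) {
  .check_tsv_rectangular(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("barcode_id", "sequence") %in% names(df)))
    stop("barcode library TSV needs columns barcode_id, sequence")
  barcode_library(df$barcode_id, df$sequence)
}
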