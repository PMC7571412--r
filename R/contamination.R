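#' Per-sample barcode cross-contamination rate
#'
#' For sample j, the cross-contamination rate is the mean read count of
#' library barcodes that are not expected in that sample, expressed as a
#' fraction of the sample's total counts:
#' B_j = (1/m * sum_i C_i) / T_j, where m is the number of library
#' barcodes not expected in j, C_i the count of contaminating barcode i,
#' and T_j the sample's total count over all library barcodes. It is the
#' amount of noise an average contaminating strain contributes to the
#' sample, and is scale-invariant in the counts.
#'
#' Rates must be computed on raw (pre-censoring) counts; censoring
#' unexpected barcodes first would force B_j = 0.
#'
#' @param sample_counts named count vector for one sample (one count
#'   matrix row), names are barcode IDs
#' @param expected character vector of barcode IDs expected in the sample
#' @param library character vector of all library barcode IDs (or a
#'   [barcode_library()])
#' @return list: sample entry with `B_j`, `m`, `contaminating_sum`, `T_j`,
#'   and `contaminant_counts` (named vector)
#' @export
contamination_rate <- function(sample_counts, expected, library) {
  if (inherits(library, "bse_library")) library <- library$barcode_id
  if (!all(expected %in% library))
    stop("expected barcodes must be a subset of the library")
  contaminants <- setdiff(library, expected)
  m <- length(contaminants)
  if (m == 0L)
    stop("expected set equals the library: m = 0, rate undefined")
  missing_ids <- setdiff(library, names(sample_counts))
  if (length(missing_ids))
    stop("sample counts missing library barcodes: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  total <- sum(sample_counts[library])
  if (total <= 0)
    stop("sample total T_j is zero: contamination rate undefined")
  csum <- sum(sample_counts[contaminants])
  list(B_j = (csum / m) / total,
       m = m,
       contaminating_sum = csum,
       T_j = total,
       contaminant_counts = sample_counts[contaminants])
}

#' Contamination report for a whole count matrix
#'
#' Applies [contamination_rate()] to every sample in the sheet. Samples
#' with zero total counts have no defined rate; they are excluded from
#' the report and listed separately in the `zero_total_samples` attribute.
#'
#' @param counts count matrix (samples x barcodes)
#' @param sheet sample sheet giving each sample's expected barcode set
#' @param library a [barcode_library()] or character vector of IDs
#' @return data.frame (sample_id, B_j, m, contaminating_sum, T_j) with
#'   attribute `zero_total_samples`
#' @export
contamination_report <- function(counts, sheet, library) {
  counts <- as_count_matrix(counts)
  miss <- setdiff(rownames(counts), sheet$sample_id)
  if (length(miss))
    stop("samples missing from sheet: ", paste(miss, collapse = ", "))
  if (inherits(library, "bse_library")) library <- library$barcode_id
  totals <- rowSums(counts)
  zero <- rownames(counts)[totals == 0]
  keep <- setdiff(rownames(counts), zero)
  rows <- lapply(keep, function(s) {
    exp_ids <- sheet$expected_barcodes[[match(s, sheet$sample_id)]]
    r <- contamination_rate(counts[s, ], exp_ids, library)
    data.frame(sample_id = s, B_j = r$B_j, m = r$m,
               contaminating_sum = r$contaminating_sum, T_j = r$T_j,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(sample_id = character(), B_j = numeric(),
                      m = integer(), contaminating_sum = numeric(),
                      T_j = numeric())
  attr(out, "zero_total_samples") <- zero
  out
}

#' Censor counts of unexpected barcodes
#'
#' Sets to zero every cell whose barcode is not in the sample's expected
#' set, leaving expected cells untouched. Idempotent. Run after
#' [contamination_report()], never before.
#'
#' @param counts count matrix
#' @param sheet sample sheet with expected barcode sets
#' @return censored count matrix
#' @export
censor_unexpected <- function(counts, sheet) {
  counts <- as_count_matrix(counts)
  miss <- setdiff(rownames(counts), sheet$sample_id)
  if (length(miss))
    stop("samples missing from sheet: ", paste(miss, collapse = ", "))
  for (s in rownames(counts)) {
    exp_ids <- sheet$expected_barcodes[[match(s, sheet$sample_id)]]
    counts[s, !(colnames(counts) %in% exp_ids)] <- 0L
  }
  counts
}

#' Pick the cleaner replicate for duplicate-sequenced samples
#'
#' When a sample was sequenced in two runs, the replicate with the lower
#' contamination rate is retained for all downstream analysis; ties go to
#' the first run.
#'
#' @param report1,report2 contamination reports sharing a sample set
#' @return data.frame (sample_id, chosen_run, B_j)
#' @export
choose_replicate_runs <- function(report1, report2) {
  common <- intersect(report1$sample_id, report2$sample_id)
  if (!length(common)) stop("no shared samples between runs")
  b1 <- report1$B_j[match(common, report1$sample_id)]
  b2 <- report2$B_j[match(common, report2$sample_id)]
  chosen <- ifelse(b2 < b1, 2L, 1L)
  data.frame(sample_id = common, chosen_run = chosen,
             B_j = pmin(b1, b2), stringsAsFactors = FALSE)
}

#' Compare contamination between two processing runs
#'
#' Weighted one-tailed paired t-test of whether contamination decreased in
#' the second run (H1: run2 < run1), with per-sample read weights.
#'
#' @param b1,b2 per-sample contamination rates, paired by position (or
#'   contamination reports, paired on sample_id)
#' @param weights per-sample weights (default equal)
#' @return list with `t`, `df`, `p_value` (one-tailed, less),
#'   `mean_difference` (run2 - run1)
#' @export
compare_contamination_runs <- function(b1, b2, weights = NULL) {
  if (is.data.frame(b1)) {
    common <- intersect(b1$sample_id, b2$sample_id)
    x1 <- b1$B_j[match(common, b1$sample_id)]
    x2 <- b2$B_j[match(common, b2$sample_id)]
  } else {
    x1 <- b1; x2 <- b2
  }
  if (length(x1) != length(x2)) stop("runs must share a sample set")
  if (length(x1) < 2L) stop("need at least 2 paired samples")
  if (is.null(weights)) weights <- rep(1, length(x1))
  res <- weighted_t_test(x2, x1, weights = weights, paired = TRUE,
                         alternative = "less")
  list(t = res$t, df = res$df, p_value = res$p_value,
       mean_difference = res$estimate)
}
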