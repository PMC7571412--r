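#' Focal-barcode proportion
#'
#' Proportion of the focal (first) barcode in a two-barcode population:
#' p = c1 / (c1 + c2). Both counts zero yields a missing value for that
#' timepoint, not an error.
#'
#' @param c1,c2 read counts of the focal and companion barcode (vectorized)
#' @export
barcode_proportions <- function(c1, c2) {
  if (any(c(c1, c2) < 0)) stop("counts must be non-negative")
  tot <- c1 + c2
  ifelse(tot > 0, c1 / tot, NA_real_)
}

#' Summarize a two-barcode proportion trajectory
#'
#' Computes the seven lineage-dynamics metrics from the focal-barcode
#' proportion time series p_t sampled at the given generations:
#' \itemize{
#'   \item m_max / t_max: magnitude and (earliest) generation of the
#'     maximum absolute change from the starting proportion, |p_t - p_0|.
#'   \item m_max_rate / t_max_rate: maximum per-generation rate of change
#'     between adjacent sampled timepoints, |p_t - p_prev| / (g_t -
#'     g_prev); the reported generation is the interval's ending
#'     generation. Rates are per generation because sampling is unevenly
#'     spaced.
#'   \item m_max_diff / t_max_diff: maximum absolute difference between
#'     the two barcodes' proportions, |p_t - (1 - p_t)| = |2 p_t - 1|.
#'   \item total_change: cumulative absolute change, sum over adjacent
#'     timepoints of |p_t - p_prev| (always >= m_max).
#' }
#' A barcode is called fixed when either member of the pair reaches a
#' proportion of 0.95 or greater at some sampled generation and maintains
#' it at every later sampled generation through the end of the series;
#' `fixation_generation` is the earliest such generation. Fixation is
#' evaluated on sampled generations only (no interpolation).
#'
#' Missing proportions are skipped: adjacent-pair metrics use the nearest
#' available neighbors, normalized by the actual generation gap. Argmax
#' ties are broken by the earliest generation.
#'
#' @param generations strictly increasing generation numbers (must
#'   include generation 0)
#' @param p focal-barcode proportion at each generation (NA = missing)
#' @return one-row data.frame: t_max, m_max, t_max_rate, m_max_rate,
#'   t_max_diff, m_max_diff, total_change, fixed, fixation_generation,
#'   initial_abundance
#' @export
summarize_trajectory <- function(generations, p) {
  stopifnot(length(generations) == length(p),
            !is.unsorted(generations, strictly = TRUE))
  keep <- !is.na(p)
  g <- generations[keep]; p <- p[keep]
  if (length(p) < 2L) stop("need >= 2 non-missing timepoints")
  if (g[1] != 0) stop("generation 0 is required")
  if (any(p < 0 | p > 1)) stop("proportions must lie in [0, 1]")

  dev <- abs(p - p[1])
  i_max <- which.max(dev)             # which.max takes the earliest tie
  rate <- abs(diff(p)) / diff(g)
  i_rate <- which.max(rate)
  bdiff <- abs(2 * p - 1)
  i_diff <- which.max(bdiff)

  major <- pmax(p, 1 - p)
  fixed_from <- rev(cumprod(rev(major >= 0.95))) == 1
  fixed <- any(fixed_from)
  fix_gen <- if (fixed) g[which(fixed_from)[1]] else NA_real_

  data.frame(t_max = g[i_max], m_max = dev[i_max],
             t_max_rate = g[i_rate + 1L], m_max_rate = rate[i_rate],
             t_max_diff = g[i_diff], m_max_diff = bdiff[i_diff],
             total_change = sum(abs(diff(p))),
             fixed = fixed, fixation_generation = fix_gen,
             initial_abundance = p[1])
}

#' Dynamics summaries for every two-barcode population
#'
#' Groups the dynamics samples of a count matrix into per-population
#' trajectories and summarizes each with [summarize_trajectory()]. Each
#' population must have exactly two expected barcodes; the focal barcode
#' is the first of the pair (using only the first barcode keeps the
#' population-level data statistically independent, since the pair's
#' proportions are complementary). Per-timepoint read weights are the
#' harmonic mean of the focal count and the sample total; the population
#' weight attached to the summary is the harmonic mean over timepoints.
#'
#' @param counts count matrix containing the dynamics samples
#' @param populations data.frame mapping samples to trajectories:
#'   columns sample_id, population_id, generation
#' @param sheet sample sheet (expected barcode sets give the pair, focal
#'   first; treatment_id is carried through)
#' @return data.frame with population_id, treatment_id, the seven metrics,
#'   fixed, fixation_generation, initial_abundance, weight
#' @export
batch_dynamics <- function(counts, populations, sheet) {
  counts <- as_count_matrix(counts)
  stopifnot(all(c("sample_id", "population_id", "generation") %in%
                  names(populations)))
  out <- list()
  for (pop in unique(populations$population_id)) {
    rows <- populations[populations$population_id == pop, ]
    rows <- rows[order(rows$generation), ]
    pair <- sheet$expected_barcodes[[match(rows$sample_id[1],
                                           sheet$sample_id)]]
    if (length(pair) != 2L)
      stop("population ", pop, " has ", length(pair),
           " expected barcodes; exactly 2 required")
    c1 <- counts[rows$sample_id, pair[1]]
    c2 <- counts[rows$sample_id, pair[2]]
    p <- barcode_proportions(c1, c2)
    wts <- mapply(function(a, tot) if (a > 0 && tot > 0)
      harmonic_weight(c(a, tot)) else 0, c1, c1 + c2)
    sm <- summarize_trajectory(rows$generation, p)
    sm$population_id <- pop
    sm$treatment_id <-
      sheet$treatment_id[match(rows$sample_id[1], sheet$sample_id)]
    sm$weight <- if (all(wts > 0)) harmonic_weight(wts) else 0
    out[[pop]] <- sm
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  cols <- c("population_id", "treatment_id", "t_max", "m_max",
            "t_max_rate", "m_max_rate", "t_max_diff", "m_max_diff",
            "total_change", "fixed", "fixation_generation",
            "initial_abundance", "weight")
  res[, cols]
}
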