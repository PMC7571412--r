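#' Malthusian fitness from a paired pooled competition assay
#'
#' The per-generation Malthusian fitness of a focal strain relative to the
#' common reference is the change in the log count ratio between the assay
#' start (0 h) and end (48 h), divided by the number of generations
#' elapsed (20 by default: two overnight cultures at ~10 generations each):
#'
#'   m = ( ln(C_48/R_48) - ln(C_0/R_0) ) / generations
#'
#' The ratio form makes m invariant to sequencing depth at each timepoint
#' and antisymmetric under swapping the focal and reference strains.
#'
#' Zero counts make the log ratios undefined. Under the default
#' `zero_policy = "pseudocount"`, 0.5 is added to all four counts of an
#' affected assay and the estimate is flagged; under `"strict"` the
#' estimate is returned as NA (flagged), never an error.
#'
#' @param c_focal_0h,c_ref_0h,c_focal_48h,c_ref_48h read counts
#'   (vectorized over assays)
#' @param generations generations elapsed between the two samplings
#' @param zero_policy "pseudocount" (default) or "strict"
#' @return numeric vector of m values with attribute `flagged` (logical:
#'   TRUE where a zero count was handled)
#' @export
malthusian_fitness <- function(c_focal_0h, c_ref_0h, c_focal_48h, c_ref_48h,
                               generations = 20,
                               zero_policy = c("pseudocount", "strict")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(all(generations > 0))
  counts <- cbind(c_focal_0h, c_ref_0h, c_focal_48h, c_ref_48h)
  if (any(counts < 0)) stop("counts must be non-negative")
  flagged <- apply(counts == 0, 1L, any)
  if (zero_policy == "pseudocount" && any(flagged))
    counts[flagged, ] <- counts[flagged, ] + 0.5
  m <- (log(counts[, 3] / counts[, 4]) - log(counts[, 1] / counts[, 2])) /
    generations
  if (zero_policy == "strict") m[flagged] <- NA_real_
  attr(m, "flagged") <- unname(flagged)
  m
}

#' Convert between Malthusian and Wrightian fitness
#'
#' Wrightian (multiplicative per-generation) fitness is w = exp(m);
#' Malthusian fitness is its log, m = ln(w). Exact inverses.
#'
#' @param m Malthusian fitness (per generation)
#' @param w Wrightian fitness (> 0)
#' @export
to_wrightian <- function(m) exp(m)

#' @rdname to_wrightian
#' @export
to_malthusian <- function(w) {
  if (any(w <= 0, na.rm = TRUE)) stop("Wrightian fitness must be positive")
  log(w)
}

#' Fitness change over the evolution experiment
#'
#' Difference in Wrightian fitness, relative to the common ancestral
#' reference, between the end and start of evolution:
#' delta_w = w_g250 - w_g0. Assumes no frequency-dependent selection.
#'
#' @param w_g0,w_g250 Wrightian fitness at generation 0 and 250
#' @export
fitness_change <- function(w_g0, w_g250) {
  stopifnot(all(is.finite(w_g0)), all(is.finite(w_g250)))
  w_g250 - w_g0
}

#' Harmonic-mean read weight
#'
#' Observation weight built from the read counts entering a derived
#' quantity (the focal-barcode count and the sample total at each
#' contributing timepoint). The harmonic mean n / sum(1/c_k) is dominated
#' by its smallest component, so a quantity computed from one low-count
#' source is down-weighted no matter how deep the other sources are. Any
#' zero component gives weight 0 (the limit case).
#'
#' @param component_counts numeric vector of contributing counts
#' @return the harmonic mean, or 0 if any component is 0
#' @export
harmonic_weight <- function(component_counts) {
  if (!length(component_counts)) stop("empty component list")
  if (any(component_counts < 0)) stop("counts must be non-negative")
  if (any(component_counts == 0)) return(0)
  length(component_counts) / sum(1 / component_counts)
}

#' Weighted replicate aggregation
#'
#' Weighted mean and weighted standard error across replicate
#' measurements. Weights are normalized to sum to the number of
#' replicates (count-weight semantics), so equal weights reduce exactly
#' to the unweighted mean and SE.
#'
#' @param values replicate values
#' @param weights positive weights (default equal)
#' @return list with `mean`, `se` (NA for a single replicate), `n`
#' @export
aggregate_replicates <- function(values, weights = NULL) {
  keep <- is.finite(values)
  values <- values[keep]
  n <- length(values)
  if (!n) stop("no finite replicate values")
  if (is.null(weights)) weights <- rep(1, n) else weights <- weights[keep]
  if (any(weights < 0) || sum(weights) == 0) stop("invalid weights")
  w <- weights * n / sum(weights)
  mu <- sum(w * values) / n
  if (n < 2L) return(list(mean = mu, se = NA_real_, n = n))
  v <- sum(w * (values - mu)^2) / (n - 1)
  list(mean = mu, se = sqrt(v / n), n = n)
}

#' Pooled root mean squared error among replicates
#'
#' The replicate-level noise scale: deviations of replicate measurements
#' from their per-strain mean, pooled over strains,
#' rMSE = sqrt( sum_i sum_r (x_ir - xbar_i)^2 / sum_i (n_i - 1) ).
#' This is the error scale fed to the power analyses.
#'
#' @param values replicate measurements
#' @param strain strain identifier per measurement
#' @return pooled rMSE
#' @export
pooled_rmse <- function(values, strain) {
  stopifnot(length(values) == length(strain))
  keep <- is.finite(values)
  values <- values[keep]; strain <- strain[keep]
  mu <- stats::ave(values, strain)
  nper <- stats::ave(values, strain, FUN = length)
  if (all(nper < 2)) stop("rMSE needs at least one replicated strain")
  ss <- sum((values - mu)^2)
  dfree <- sum(tapply(values, strain, length) - 1)
  sqrt(ss / dfree)
}

#' Per-strain significance with FDR control
#'
#' Fits a zero-intercept weighted linear model of the replicate values on
#' strain indicators (equivalent to per-strain weighted means tested
#' against 0 with a model-pooled residual variance), then applies
#' Benjamini-Hochberg adjustment. Two-sided tests suit deviations of
#' initial fitness from the mean; one-tailed "greater" suits fitness
#' change, where the question is whether fitness increased.
#'
#' @param data data.frame with columns `strain`, `value`, and optionally
#'   `weight`
#' @param tail "two.sided" or "greater"
#' @return data.frame (strain, estimate, se, t, df, p_value, q_value, n)
#' @export
strain_significance <- function(data, tail = c("two.sided", "greater")) {
  tail <- match.arg(tail)
  stopifnot(all(c("strain", "value") %in% names(data)))
  data <- data[is.finite(data$value), , drop = FALSE]
  w <- if ("weight" %in% names(data)) data$weight else rep(1, nrow(data))
  if (any(w < 0)) stop("weights must be non-negative")
  nrep <- table(data$strain)
  if (any(nrep < 2L))
    stop("strains with < 2 replicates: ",
         paste(names(nrep)[nrep < 2], collapse = ", "))
  data$strain <- factor(data$strain)
  fit <- stats::lm(value ~ 0 + strain, data = data, weights = w)
  sm <- summary(fit)$coefficients
  strain_names <- sub("^strain", "", rownames(sm))
  tval <- sm[, "t value"]
  # a zero estimate with zero residual variance is no evidence, not NaN
  tval[!is.finite(tval) & sm[, "Estimate"] == 0] <- 0
  dfree <- fit$df.residual
  p <- if (tail == "two.sided") 2 * stats::pt(abs(tval), dfree,
                                              lower.tail = FALSE)
       else stats::pt(tval, dfree, lower.tail = FALSE)
  data.frame(strain = strain_names,
             estimate = unname(sm[, "Estimate"]),
             se = unname(sm[, "Std. Error"]),
             t = unname(tval),
             df = dfree,
             p_value = unname(p),
             q_value = bh_fdr(unname(p)),
             n = as.integer(nrep[strain_names]),
             stringsAsFactors = FALSE)
}

#' Fitness estimates for every assay in a manifest
#'
#' The assay manifest pairs 0 h and 48 h samples of each pooled
#' competition assay. One row per (pool, replicate, timepoint) with
#' columns: pool_id, replicate, timepoint, sample_0h, sample_48h,
#' reference_barcode. Every expected barcode of the pool other than the
#' reference is treated as focal. The per-estimate read weight is the
#' harmonic mean of the four counts entering the estimate: focal count
#' and sample total at each of the two timepoints.
#'
#' @param counts count matrix holding the assay samples (censored)
#' @param manifest assay manifest data.frame (see Details)
#' @param sheet sample sheet (provides expected barcode sets)
#' @param generations assay generations (default 20)
#' @param zero_policy passed to [malthusian_fitness()]
#' @return data.frame (strain, pool_id, replicate, timepoint, m, w,
#'   weight, focal_0h, focal_48h, total_0h, total_48h, flagged)
#' @export
assay_fitness <- function(counts, manifest, sheet, generations = 20,
                          zero_policy = "pseudocount") {
  counts <- as_count_matrix(counts)
  needed <- c("pool_id", "replicate", "timepoint", "sample_0h",
              "sample_48h", "reference_barcode")
  miss <- setdiff(needed, names(manifest))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  out <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    s0 <- row$sample_0h; s48 <- row$sample_48h
    if (!all(c(s0, s48) %in% rownames(counts)))
      stop("manifest sample absent from counts: ", s0, " / ", s48)
    pool_bc <- sheet$expected_barcodes[[match(s0, sheet$sample_id)]]
    focal <- setdiff(pool_bc, row$reference_barcode)
    t0 <- sum(counts[s0, pool_bc]); t48 <- sum(counts[s48, pool_bc])
    r0 <- counts[s0, row$reference_barcode]
    r48 <- counts[s48, row$reference_barcode]
    f0 <- counts[s0, focal]; f48 <- counts[s48, focal]
    m <- malthusian_fitness(f0, rep(r0, length(focal)),
                            f48, rep(r48, length(focal)),
                            generations = generations,
                            zero_policy = zero_policy)
    wt <- mapply(function(a, b) harmonic_weight(c(a, t0, b, t48)), f0, f48)
    out[[i]] <- data.frame(strain = focal, pool_id = row$pool_id,
                           replicate = row$replicate,
                           timepoint = row$timepoint,
                           m = as.numeric(m), w = exp(as.numeric(m)),
                           weight = as.numeric(wt),
                           focal_0h = as.numeric(f0),
                           focal_48h = as.numeric(f48),
                           total_0h = t0, total_48h = t48,
                           flagged = attr(m, "flagged"),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-strain fitness-change records
#'
#' Combines generation-0 and generation-250 assay estimates into per-strain
#' fitness change. When the replicate sets of the two timepoints agree,
#' delta_w is computed replicate-by-replicate (w_g250 - w_g0 within each
#' replicate) and the replicate values are aggregated with harmonic-read
#' weights; otherwise delta_w is the difference of the timepoint weighted
#' means with SE propagated in quadrature. One-tailed (greater) per-strain
#' tests with BH adjustment ask which strains increased in fitness.
#'
#' @param estimates output of [assay_fitness()] with timepoints
#'   "generation-0" and "generation-250"
#' @return list with `records` (per-strain data.frame: strain, delta_w,
#'   se_delta_w, weight, p_value, q_value, median_count, n_replicates)
#'   and `replicates` (per-replicate delta_w table)
#' @export
fitness_change_records <- function(estimates) {
  tps <- c("generation-0", "generation-250")
  if (!all(tps %in% estimates$timepoint))
    stop("estimates must contain both generation-0 and generation-250")
  g0 <- estimates[estimates$timepoint == tps[1], ]
  g250 <- estimates[estimates$timepoint == tps[2], ]
  strains <- intersect(unique(g0$strain), unique(g250$strain))
  reps <- list(); recs <- list()
  for (s in strains) {
    a <- g0[g0$strain == s, ]; b <- g250[g250$strain == s, ]
    common <- intersect(a$replicate, b$replicate)
    if (length(common) == length(a$replicate) &&
        length(common) == length(b$replicate) && length(common) >= 1L) {
      aa <- a[match(common, a$replicate), ]
      bb <- b[match(common, b$replicate), ]
      dw <- fitness_change(aa$w, bb$w)
      wt <- mapply(function(x, y) if (x > 0 && y > 0)
        2 / (1 / x + 1 / y) else 0, aa$weight, bb$weight)
      reps[[s]] <- data.frame(strain = s, replicate = common,
                              delta_w = dw, weight = wt,
                              stringsAsFactors = FALSE)
      # a strain absent from the reads (all-zero focal counts) has zero
      # harmonic weights; aggregate unweighted so the record survives
      agg <- aggregate_replicates(dw, if (all(wt == 0)) NULL else wt)
      recs[[s]] <- data.frame(strain = s, delta_w = agg$mean,
                              se_delta_w = agg$se,
                              weight = if (all(wt == 0)) 0 else
                                harmonic_weight(wt[wt > 0]),
                              median_count = stats::median(
                                c(aa$focal_0h, aa$focal_48h,
                                  bb$focal_0h, bb$focal_48h)),
                              n_replicates = length(common),
                              stringsAsFactors = FALSE)
    } else {
      m0 <- aggregate_replicates(a$w, a$weight)
      m1 <- aggregate_replicates(b$w, b$weight)
      recs[[s]] <- data.frame(strain = s,
                              delta_w = m1$mean - m0$mean,
                              se_delta_w = sqrt(m0$se^2 + m1$se^2),
                              weight = harmonic_weight(
                                c(a$weight, b$weight)),
                              median_count = stats::median(
                                c(a$focal_0h, a$focal_48h,
                                  b$focal_0h, b$focal_48h)),
                              n_replicates = min(nrow(a), nrow(b)),
                              stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  replicates <- do.call(rbind, c(reps, list(make.row.names = FALSE)))
  records$p_value <- NA_real_
  records$q_value <- NA_real_
  if (!is.null(replicates)) {
    # strains whose reads vanished entirely carry no testable signal;
    # test the rest
    wsum <- tapply(replicates$weight, replicates$strain, sum)
    testable <- names(wsum)[wsum > 0]
    sub <- replicates[replicates$strain %in% testable, ]
    sub <- sub[sub$weight > 0, ]
    nrep <- table(sub$strain)
    sub <- sub[sub$strain %in% names(nrep)[nrep >= 2L], ]
    if (length(unique(sub$strain)) >= 2L) {
      sig <- strain_significance(
        data.frame(strain = sub$strain, value = sub$delta_w,
                   weight = sub$weight), tail = "greater")
      idx <- match(records$strain, sig$strain)
      records$p_value <- sig$p_value[idx]
      records$q_value <- sig$q_value[idx]
    }
  }
  list(records = records, replicates = replicates)
}
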