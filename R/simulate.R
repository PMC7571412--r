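#' Default treatment set for synthetic studies
#'
#' Six serial-transfer treatments: the standard-condition control
#' (diploid, complete medium, 1:1000 transfer; 21 populations), ethanol
#' and NaCl stress (1:1000), increased (1:4000) and reduced (1:250)
#' dilution, and a haploid arm (1:1000), with 11 populations each —
#' 76 two-barcode populations in all. The mutation-supply parameters
#' (per-cell per-generation beneficial rate U and exponential mean effect
#' s_mean) are illustrative: no direct measurements exist for them, so
#' they are set to produce qualitatively realistic regimes (appreciable
#' adaptation and occasional fixation under the stronger-selection arms).
#'
#' @return data.frame (treatment_id, dilution, n_populations, ploidy, U,
#'   s_mean)
#' @export
default_treatments <- function() {
  data.frame(
    treatment_id = c("CM_diploid_1to1000", "CM_EtOH_1to1000",
                     "CM_NaCl_1to1000", "CM_diploid_1to4000",
                     "CM_diploid_1to250", "CM_haploid_1to1000"),
    dilution = c(1000, 1000, 1000, 4000, 250, 1000),
    n_populations = c(21L, 11L, 11L, 11L, 11L, 11L),
    ploidy = c("diploid", "diploid", "diploid", "diploid", "diploid",
               "haploid"),
    U = c(5e-8, 5e-8, 1e-7, 5e-8, 5e-8, 2e-7),
    s_mean = c(0.02, 0.015, 0.05, 0.02, 0.02, 0.04),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles the generative parameterization of a synthetic study:
#' serial-dilution evolution of two-barcode populations under the six
#' treatments, with multinomial read sampling at the seven sampling
#' generations, paired 0 h/48 h pooled assays in four replicates, and
#' diffuse cross-contamination.
#'
#' @param seed RNG seed recorded with every artifact
#' @param treatments treatment table (see [default_treatments()])
#' @param days serial-transfer days (default 25)
#' @param barcodes_per_population lineages founding each population
#' @param saturation_density cells/ml at saturation (default 3.0e8)
#' @param volume culture volume, ml (default 0.6)
#' @param depth sequencing depth per barcode per sample (default 3000,
#'   matching a median of ~3,000 reads per barcode)
#' @param beta diffuse cross-contamination rate per sample (default
#'   4e-4, i.e. 0.04%)
#' @param assay_generations generations per pooled assay (default 20)
#' @param assay_noise_sd replicate-level biological noise on per-assay
#'   Malthusian fitness (per generation; default 0.03, which yields a
#'   replicate fitness-change error near the 4e-2 scale real end-point
#'   assays show)
#' @param sampling_days days at which dynamics samples are drawn
#' @param generation_labels generation labels for those days
#' @param deterministic_mode replace all sampling by expectations
#' @return list of class `bse_sim_config`
#' @export
sim_config <- function(seed = 1L,
                       treatments = default_treatments(),
                       days = 25L,
                       barcodes_per_population = 2L,
                       saturation_density = 3.0e8,
                       volume = 0.6,
                       depth = 3000L,
                       beta = 4e-4,
                       assay_generations = 20,
                       assay_noise_sd = 0.03,
                       sampling_days = c(0, 10, 15, 20, 22, 24, 25),
                       generation_labels = c(0, 100, 150, 200, 220, 240,
                                             250),
                       deterministic_mode = FALSE) {
  stopifnot(all(treatments$dilution > 1), days >= 1,
            barcodes_per_population >= 1, depth >= 0,
            beta >= 0, beta < 1,
            length(sampling_days) == length(generation_labels))
  structure(list(seed = as.integer(seed), treatments = treatments,
                 days = as.integer(days),
                 barcodes_per_population = as.integer(
                   barcodes_per_population),
                 saturation_density = saturation_density, volume = volume,
                 depth = as.integer(depth), beta = beta,
                 assay_generations = assay_generations,
                 assay_noise_sd = assay_noise_sd,
                 sampling_days = sampling_days,
                 generation_labels = generation_labels,
                 deterministic_mode = deterministic_mode),
            class = "bse_sim_config")
}

#' Simulate serial-transfer evolution of one population
#'
#' Daily cycle: (i) deterministic within-day growth, each genotype class
#' growing in proportion to exp(s * g) over g = log2(dilution)
#' generations, renormalized to saturation; (ii) a multinomial bottleneck
#' of N_b = saturation * volume / dilution cells at transfer; (iii)
#' Poisson(U * N_b * g) new beneficial genotypes per day, each founding a
#' class nested within its parent's barcode with effect s_parent +
#' Exponential(mean = s_mean). A barcode's proportion is the summed
#' frequency of its classes. In deterministic mode the bottleneck and
#' mutation steps are skipped, so trajectories follow the logistic closed
#' form exactly (two classes with advantage s satisfy
#' r_t = r_0 * exp(s t) in the ratio).
#'
#' @param dilution daily dilution factor D
#' @param days number of transfer cycles
#' @param init data.frame describing founding classes: columns `barcode`
#'   (lineage label), `s` (Malthusian advantage per generation), `freq`
#'   (initial frequency; must sum to 1)
#' @param U beneficial mutation rate per cell per generation
#' @param s_mean mean of the exponential effect-size distribution
#' @param saturation_density,volume culture parameters (set N_b)
#' @param deterministic_mode skip bottleneck sampling and mutation
#' @param sampling_days days to record (day 0 = founding state)
#' @param generation_labels labels for the recorded timepoints
#' @return list: `proportions` (barcode x timepoint matrix),
#'   `mean_fitness` (barcode x timepoint matrix of class-frequency
#'   weighted mean s within each barcode), `generations` (labels),
#'   `classes` (final class table)
#' @export
simulate_serial_transfer <- function(dilution, days = 25, init,
                                     U = 0, s_mean = 0.02,
                                     saturation_density = 3.0e8,
                                     volume = 0.6,
                                     deterministic_mode = FALSE,
                                     sampling_days = c(0, 10, 15, 20, 22,
                                                       24, 25),
                                     generation_labels = NULL) {
  stopifnot(is.data.frame(init),
            all(c("barcode", "s", "freq") %in% names(init)))
  if (abs(sum(init$freq) - 1) > 1e-8)
    stop("initial frequencies must sum to 1")
  g <- log2(dilution)
  N_b <- saturation_density * volume / dilution
  if (N_b < 1) stop("bottleneck below one cell; check parameters")
  if (is.null(generation_labels)) generation_labels <- sampling_days * g
  barcodes <- unique(init$barcode)
  classes <- data.frame(barcode = init$barcode, s = init$s,
                        freq = init$freq, stringsAsFactors = FALSE)

  snap_p <- matrix(NA_real_, length(barcodes), length(sampling_days),
                   dimnames = list(barcodes, generation_labels))
  snap_m <- snap_p
  record <- function(day) {
    j <- match(day, sampling_days)
    if (is.na(j)) return()
    for (b in barcodes) {
      sel <- classes$barcode == b
      pb <- sum(classes$freq[sel])
      snap_p[b, j] <<- pb
      snap_m[b, j] <<- if (pb > 0)
        sum(classes$freq[sel] * classes$s[sel]) / pb else NA_real_
    }
  }
  record(0)

  for (day in seq_len(days)) {
    # within-day growth (deterministic exponential with selection)
    grown <- classes$freq * exp(classes$s * g)
    classes$freq <- grown / sum(grown)
    if (!deterministic_mode) {
      # bottleneck: multinomial sample of N_b cells
      n <- stats::rmultinom(1, round(N_b), classes$freq)[, 1]
      keep <- n > 0
      classes <- classes[keep, , drop = FALSE]
      classes$freq <- n[keep] / sum(n)
      # beneficial mutation arrivals
      if (U > 0) {
        n_mut <- stats::rpois(1, U * N_b * g)
        if (n_mut > 0) {
          parent <- sample.int(nrow(classes), n_mut, replace = TRUE,
                               prob = classes$freq)
          eff <- classes$s[parent] + stats::rexp(n_mut, rate = 1 / s_mean)
          newc <- data.frame(barcode = classes$barcode[parent],
                             s = eff, freq = 1 / N_b,
                             stringsAsFactors = FALSE)
          classes$freq[parent] <- pmax(classes$freq[parent] - 1 / N_b, 0)
          classes <- rbind(classes, newc)
          classes$freq <- classes$freq / sum(classes$freq)
        }
      }
    }
    record(day)
  }
  list(proportions = snap_p, mean_fitness = snap_m,
       generations = generation_labels, classes = classes)
}

#' Inject diffuse cross-contamination into one sample's counts
#'
#' Adds counts for library barcodes outside the sample's expected set so
#' that the expected per-sample contamination rate (mean contaminating
#' count over total count) equals `beta`. With m contaminants and an
#' uncontaminated total T0, each contaminant receives expectation
#' beta * T0 / (1 - m beta) counts (Poisson-sampled unless deterministic,
#' where the rounded expectation is used), which makes the measured rate
#' on the final total equal beta in expectation.
#'
#' @param row named count vector over the full library
#' @param beta target contamination rate (0 <= beta, m * beta < 1)
#' @param library barcode IDs of the full library
#' @param expected barcode IDs expected in the sample
#' @param deterministic_mode use rounded expectations
#' @return the row with contaminating counts added
#' @export
inject_contamination <- function(row, beta, library, expected,
                                 deterministic_mode = FALSE) {
  if (inherits(library, "bse_library")) library <- library$barcode_id
  stopifnot(beta >= 0, beta < 1)
  contaminants <- setdiff(library, expected)
  m <- length(contaminants)
  if (m == 0L) {
    warning("expected set equals library; nothing to contaminate")
    return(row)
  }
  if (beta == 0) return(row)
  if (m * beta >= 1) stop("m * beta >= 1: contamination rate infeasible")
  t0 <- sum(row[expected])
  mu <- beta * t0 / (1 - m * beta)
  add <- if (deterministic_mode) round(rep(mu, m)) else
    stats::rpois(m, mu)
  row[contaminants] <- row[contaminants] + add
  row
}

#' Simulate one paired 0 h/48 h pooled competition assay
#'
#' The 0 h sample is a multinomial draw at the configured pool
#' proportions; 48 h expected proportions are the 0 h proportions
#' reweighted by exp(m * generations) per strain and multinomially
#' sampled. Cross-contamination at rate `beta` is spread uniformly over
#' non-pool library barcodes before sampling. In deterministic mode both
#' samples are rounded expectations, so the count ratio of a strain with
#' advantage s against the reference changes by exactly
#' exp(s * generations).
#'
#' @param m named vector of Malthusian fitness per generation for every
#'   pool member (reference included, typically at 0)
#' @param proportions0 named initial proportions of the pool members
#'   (must sum to 1)
#' @param depth reads per barcode (total depth = depth * pool size)
#' @param generations assay generations (default 20)
#' @param beta cross-contamination rate
#' @param library full library barcode IDs (for contamination targets);
#'   defaults to the pool only (no contamination targets)
#' @param deterministic_mode use rounded expectations
#' @return list: `counts_0h`, `counts_48h` (named vectors over the full
#'   library), `truth` (m, p0, p48 over pool members)
#' @export
simulate_pooled_assay <- function(m, proportions0, depth = 3000,
                                  generations = 20, beta = 0,
                                  library = names(m),
                                  deterministic_mode = FALSE) {
  if (inherits(library, "bse_library")) library <- library$barcode_id
  pool <- names(m)
  if (is.null(pool) || is.null(names(proportions0)))
    stop("m and proportions0 must be named by barcode ID")
  if (depth <= 0) stop("depth must be positive")
  if (!setequal(pool, names(proportions0)))
    stop("m and proportions0 must cover the same pool")
  proportions0 <- proportions0[pool]
  if (abs(sum(proportions0) - 1) > 1e-8)
    stop("initial proportions must sum to 1")
  total <- round(depth * length(pool))
  p48 <- proportions0 * exp(m * generations)
  p48 <- p48 / sum(p48)

  contaminants <- setdiff(library, pool)
  mcont <- length(contaminants)
  draw <- function(p_pool) {
    p_full <- stats::setNames(numeric(length(library)), library)
    if (mcont > 0L && beta > 0) {
      if (mcont * beta >= 1) stop("m * beta >= 1: infeasible")
      p_full[pool] <- p_pool * (1 - mcont * beta)
      p_full[contaminants] <- beta
    } else p_full[pool] <- p_pool
    if (deterministic_mode) round(total * p_full) else
      stats::rmultinom(1, total, p_full)[, 1]
  }
  list(counts_0h = draw(proportions0), counts_48h = draw(p48),
       truth = list(m = m, p0 = proportions0, p48 = p48))
}

#' Emit a FASTQ file from a count matrix
#'
#' Closes the loop for demultiplexer testing: writes one read per count
#' (sample index pair + spacers + barcode per the layout), optionally
#' corrupted by a uniform per-base substitution rate. With error rate 0,
#' [demultiplex()] recovers the count matrix exactly.
#'
#' @param counts count matrix (samples x barcodes)
#' @param sheet sample sheet giving each sample's index pair
#' @param library a [barcode_library()]
#' @param layout a [read_layout()]
#' @param path output FASTQ path (".gz" for gzip)
#' @param error_rate per-base substitution probability (default 0)
#' @param shuffle permute read order (default TRUE; order never matters
#'   to counting, but interleaved files are the realistic case)
#' @return invisible data.frame truth table (read_id, sample_id,
#'   barcode_id)
#' @export
emit_fastq <- function(counts, sheet, library, layout = read_layout(),
                       path, error_rate = 0, shuffle = TRUE) {
  counts <- as_count_matrix(counts)
  seq_of <- stats::setNames(library$sequence, library$barcode_id)
  rev_ix <- stats::setNames(sheet$rev_index, sheet$sample_id)
  if (layout$reverse_index_orientation == "reverse-complement")
    rev_ix[] <- reverse_complement(rev_ix)
  fwd_ix <- stats::setNames(sheet$fwd_index, sheet$sample_id)

  nz <- which(counts > 0, arr.ind = TRUE)
  if (nrow(nz)) {
    samples <- rownames(counts)[nz[, 1]]
    bcs <- colnames(counts)[nz[, 2]]
    reps <- counts[nz]
    reads <- paste0(fwd_ix[samples], layout$forward_spacer,
                    seq_of[bcs], layout$reverse_spacer, rev_ix[samples])
    reads <- rep(reads, reps)
    truth <- data.frame(sample_id = rep(samples, reps),
                        barcode_id = rep(bcs, reps),
                        stringsAsFactors = FALSE)
  } else {
    reads <- character(0)
    truth <- data.frame(sample_id = character(), barcode_id = character())
  }
  if (shuffle && length(reads)) {
    ord <- sample.int(length(reads))
    reads <- reads[ord]
    truth <- truth[ord, , drop = FALSE]
  }
  if (error_rate > 0 && length(reads)) {
    lens <- nchar(reads)
    nerr <- stats::rbinom(length(reads), lens, error_rate)
    for (i in which(nerr > 0)) {
      ch <- strsplit(reads[i], "")[[1]]
      pos <- sample.int(lens[i], nerr[i])
      ch[pos] <- vapply(ch[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      reads[i] <- paste(ch, collapse = "")
    }
  }
  ids <- sprintf("read_%06d", seq_along(reads))
  truth$read_id <- ids
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(reads)) {
    qual <- strrep("I", nchar(reads))
    writeLines(paste0("@", ids, "\n", reads, "\n+\n", qual), con)
  }
  invisible(truth[, c("read_id", "sample_id", "barcode_id")])
}

# Random DNA strings of the given lengths.
.random_dna <- function(n, len) {
  vapply(rep(len, length.out = n), function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
          collapse = ""), character(1))
}

# A library of n random barcodes with pairwise Hamming distance >= 6.
.random_library <- function(ids, barcode_length = 20, min_distance = 6) {
  repeat {
    lib <- barcode_library(ids, .random_dna(length(ids), barcode_length))
    v <- validate_library(lib, min_distance)
    if (v$pass) return(lib)
  }
}

# n unique index sequences with no strict-prefix ambiguity.
.random_indices <- function(n, len_range = c(9L, 12L)) {
  repeat {
    lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
    idx <- .random_dna(n, lens)
    if (!anyDuplicated(idx) && !.has_prefix_ambiguity(idx)) return(idx)
  }
}

#' Generate a complete synthetic study
#'
#' One call produces a desk-scale analogue of the full experiment:
#' 76 two-barcode populations evolved for 25 days under the six
#' treatments with dynamics samples at the seven sampling generations
#' (76 x 7 = 532 samples), plus paired 0 h/48 h pooled competition
#' assays of all 152 strains against ploidy-matched references at
#' generation 0 and generation 250 in four replicates (152 x 2 x 4 =
#' 1,216 fitness measurements), with multinomial read sampling at the
#' configured depth and diffuse cross-contamination at rate `beta`
#' injected into every sample. The ground truth (true fitness and
#' proportion trajectories, true fitness change, fixation truth by the
#' 0.95-through-end rule on true proportions) is returned alongside.
#'
#' @param config a [sim_config()]
#' @return list: `config`, `library` ([barcode_library()]), `sheet`
#'   (sample sheet covering all samples), `counts` (count matrix),
#'   `populations` (sample -> population/generation map), `manifest`
#'   (assay manifest for [assay_fitness()]), `truth` (list with
#'   `dynamics` truth data.frame, `fitness` truth data.frame, `beta`)
#' @export
generate_study <- function(config = sim_config()) {
  set.seed(config$seed)
  tr <- config$treatments
  n_pop <- sum(tr$n_populations)
  pop_treatment <- rep(tr$treatment_id, tr$n_populations)
  pop_ids <- sprintf("pop%02d", seq_len(n_pop))
  n_strains <- n_pop * config$barcodes_per_population
  strain_ids <- sprintf("bc%03d", seq_len(n_strains))
  refs <- c(diploid = "d_ref", haploid = "h_ref")
  lib <- .random_library(c(strain_ids, unname(refs)))

  pair_of <- split(strain_ids,
                   rep(seq_len(n_pop), each = config$barcodes_per_population))
  gl <- config$generation_labels

  # --- evolve populations and build dynamics samples ------------------
  sheet_rows <- list(); pop_rows <- list(); count_rows <- list()
  dyn_truth <- list(); fit_truth <- list()
  for (k in seq_len(n_pop)) {
    trt <- tr[tr$treatment_id == pop_treatment[k], ]
    pair <- pair_of[[k]]
    init <- data.frame(barcode = pair, s = 0,
                       freq = rep(1 / length(pair), length(pair)))
    sim <- simulate_serial_transfer(
      dilution = trt$dilution, days = config$days, init = init,
      U = trt$U, s_mean = trt$s_mean,
      saturation_density = config$saturation_density,
      volume = config$volume,
      deterministic_mode = config$deterministic_mode,
      sampling_days = config$sampling_days, generation_labels = gl)
    p_focal <- sim$proportions[pair[1], ]
    major <- pmax(p_focal, 1 - p_focal)
    fixed_from <- rev(cumprod(rev(major >= 0.95))) == 1
    dyn_truth[[k]] <- data.frame(
      population_id = pop_ids[k], treatment_id = pop_treatment[k],
      generation = gl, p_focal = unname(p_focal),
      fixed_truth = any(fixed_from), stringsAsFactors = FALSE)
    for (b in seq_along(pair)) {
      m0 <- sim$mean_fitness[pair[b], 1]
      m1 <- sim$mean_fitness[pair[b], length(gl)]
      if (is.na(m1)) m1 <- 0   # lineage extinct: no cells to assay
      fit_truth[[paste(k, b)]] <- data.frame(
        strain = pair[b], population_id = pop_ids[k],
        treatment_id = pop_treatment[k],
        ploidy = trt$ploidy, m_g0 = m0, m_g250 = m1,
        delta_w_truth = exp(m1) - exp(m0),
        p_final = unname(sim$proportions[pair[b], length(gl)]),
        stringsAsFactors = FALSE)
    }
    # one sequencing sample per sampled generation
    for (j in seq_along(gl)) {
      sid <- sprintf("dyn_%s_g%03d", pop_ids[k], gl[j])
      total <- config$depth * length(pair)
      pvec <- sim$proportions[pair, j]
      cnt <- if (config$deterministic_mode) round(total * pvec) else
        stats::rmultinom(1, total, pvec)[, 1]
      row <- stats::setNames(integer(nrow(lib)), lib$barcode_id)
      row[pair] <- cnt
      row <- inject_contamination(row, config$beta, lib$barcode_id, pair,
                                  config$deterministic_mode)
      count_rows[[sid]] <- row
      sheet_rows[[sid]] <- data.frame(
        sample_id = sid, fwd_index = NA, rev_index = NA,
        expected_barcodes = I(list(pair)), pool_id = pop_ids[k],
        treatment_id = pop_treatment[k],
        timepoint = sprintf("generation-%d", gl[j]), replicate = 1L,
        stringsAsFactors = FALSE)
      pop_rows[[sid]] <- data.frame(
        sample_id = sid, population_id = pop_ids[k], generation = gl[j],
        stringsAsFactors = FALSE)
    }
  }
  fit_truth <- do.call(rbind, c(fit_truth, list(make.row.names = FALSE)))

  # --- pooled end-point assays ---------------------------------------
  # pools are ploidy-pure (strains compete against a ploidy-matched
  # reference) with 8-22 barcodes per pool
  manifest <- list()
  for (pl in unique(fit_truth$ploidy)) {
    strains <- unique(fit_truth$strain[fit_truth$ploidy == pl])
    n_pools <- max(1L, ceiling(length(strains) / 19))
    assign_pool <- rep(seq_len(n_pools), length.out = length(strains))
    for (pool_i in seq_len(n_pools)) {
      focal <- strains[assign_pool == pool_i]
      ref <- unname(refs[pl])
      pool_id <- sprintf("%spool%d", substr(pl, 1, 1), pool_i)
      members <- c(focal, ref)
      # reference at 50%, focal strains sharing the other 50% equally
      p0 <- stats::setNames(
        c(rep(0.5 / length(focal), length(focal)), 0.5), members)
      for (tp in c("generation-0", "generation-250")) {
        m_true <- stats::setNames(numeric(length(members)), members)
        if (tp == "generation-250") {
          idx <- match(focal, fit_truth$strain)
          m_true[focal] <- fit_truth$m_g250[idx]
        }
        for (r in 1:4) {
          m_assay <- m_true
          if (!config$deterministic_mode && config$assay_noise_sd > 0)
            m_assay[focal] <- m_true[focal] +
              stats::rnorm(length(focal), 0, config$assay_noise_sd)
          sim <- simulate_pooled_assay(
            m_assay, p0, depth = config$depth,
            generations = config$assay_generations, beta = config$beta,
            library = lib$barcode_id,
            deterministic_mode = config$deterministic_mode)
          for (hh in c("0h", "48h")) {
            sid <- sprintf("assay_%s_%s_r%d_%s", pool_id,
                           sub("generation-", "g", tp), r, hh)
            count_rows[[sid]] <-
              if (hh == "0h") sim$counts_0h else sim$counts_48h
            sheet_rows[[sid]] <- data.frame(
              sample_id = sid, fwd_index = NA, rev_index = NA,
              expected_barcodes = I(list(members)), pool_id = pool_id,
              treatment_id = pl, timepoint = tp, replicate = r,
              stringsAsFactors = FALSE)
          }
          manifest[[paste(pool_id, tp, r)]] <- data.frame(
            pool_id = pool_id, replicate = r, timepoint = tp,
            sample_0h = sprintf("assay_%s_%s_r%d_0h", pool_id,
                                sub("generation-", "g", tp), r),
            sample_48h = sprintf("assay_%s_%s_r%d_48h", pool_id,
                                 sub("generation-", "g", tp), r),
            reference_barcode = ref, stringsAsFactors = FALSE)
        }
      }
    }
  }

  sheet <- do.call(rbind, c(sheet_rows, list(make.row.names = FALSE)))
  n_samp <- nrow(sheet)
  # index pairs: a forward x reverse grid large enough for all samples
  n_fwd <- ceiling(sqrt(n_samp))
  fwd_set <- .random_indices(n_fwd)
  rev_set <- .random_indices(ceiling(n_samp / n_fwd))
  grid <- expand.grid(f = fwd_set, r = rev_set,
                      stringsAsFactors = FALSE)[seq_len(n_samp), ]
  sheet$fwd_index <- grid$f
  sheet$rev_index <- grid$r

  counts <- do.call(rbind, count_rows)
  storage.mode(counts) <- "integer"

  list(config = config, library = lib, sheet = sheet, counts = counts,
       populations = do.call(rbind, c(pop_rows,
                                      list(make.row.names = FALSE))),
       manifest = do.call(rbind, c(manifest,
                                   list(make.row.names = FALSE))),
       truth = list(dynamics = do.call(rbind, c(dyn_truth,
                                                list(make.row.names = FALSE))),
                    fitness = fit_truth, beta = config$beta))
}
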