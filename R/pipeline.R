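#' Run the full analysis pipeline on a study
#'
#' Fixed stage order: contamination rates on raw counts, censoring of
#' unexpected barcodes, per-assay fitness estimation and fitness-change
#' records with per-strain FDR-controlled tests, per-population dynamics
#' summaries, and the treatment-level weighted models. Accepts either an
#' in-memory study (the output of [generate_study()], or an equivalent
#' list with counts/sheet/library/populations/manifest) or paths to the
#' corresponding TSV files. The run manifest records the seed, input
#' checksums, and per-stage row counts; reruns with the same inputs are
#' bit-identical because every stage is a pure function of its inputs.
#'
#' @param study list with `counts`, `sheet`, `library`, `populations`,
#'   `manifest` (see [generate_study()]), or a list of file paths with
#'   those names
#' @param fdr_levels FDR thresholds reported in the summary (default
#'   0.05 and 0.01)
#' @param assay_generations generations per pooled assay (default 20)
#' @param drop_threshold covariate-dropping p threshold for the
#'   treatment-level models (default 0.05)
#' @return list of class `bse_run`: contamination, counts_censored,
#'   estimates, fitness (records + replicates), dynamics, models,
#'   summary, manifest
#' @export
run_pipeline <- function(study, fdr_levels = c(0.05, 0.01),
                         assay_generations = 20, drop_threshold = 0.05) {
  if (all(vapply(study[c("counts", "sheet", "library")], is.character,
                 logical(1)))) {
    study <- list(counts = read_count_matrix(study$counts),
                  sheet = read_sample_sheet(study$sheet),
                  library = read_barcode_library(study$library),
                  populations = utils::read.delim(study$populations,
                                                  stringsAsFactors = FALSE),
                  manifest = utils::read.delim(study$manifest,
                                               stringsAsFactors = FALSE))
  }
  needed <- c("counts", "sheet", "library", "populations", "manifest")
  miss <- setdiff(needed, names(study))
  if (length(miss))
    stop("study is missing component(s): ", paste(miss, collapse = ", "))

  counts <- as_count_matrix(study$counts)
  contam <- contamination_report(counts, study$sheet, study$library)
  censored <- censor_unexpected(counts, study$sheet)

  estimates <- assay_fitness(censored, study$manifest, study$sheet,
                             generations = assay_generations)
  fitness <- fitness_change_records(estimates)

  dynamics <- batch_dynamics(censored, study$populations, study$sheet)

  # carry contamination and treatment onto the per-strain records for the
  # treatment-level models: each strain's contamination covariate is the
  # mean rate over its assay samples
  recs <- fitness$records
  strain_trt <- .strain_treatments(study$sheet, study$manifest)
  recs$treatment_id <- strain_trt[recs$strain]
  recs$contamination <- .strain_contamination(contam, study$sheet,
                                              recs$strain)
  repl <- fitness$replicates
  if (!is.null(repl)) {
    repl$treatment_id <- strain_trt[repl$strain]
    repl$contamination <- recs$contamination[match(repl$strain,
                                                   recs$strain)]
  }

  models <- list()
  if (!is.null(repl) && length(unique(repl$treatment_id)) >= 2L) {
    dat <- data.frame(delta_w = repl$delta_w,
                      treatment_id = repl$treatment_id,
                      contamination = repl$contamination,
                      strain = repl$strain, weight = repl$weight)
    dat <- dat[dat$weight > 0, ]
    models$fitness_change_treatment <-
      fit_treatment_model(dat, drop_threshold)
  }
  if (length(unique(dynamics$treatment_id)) >= 2L)
    models$dynamics <- fit_dynamics_models(dynamics, drop_threshold)

  summary <- list(
    n_samples = nrow(counts),
    n_dynamics_samples = nrow(study$populations),
    n_fitness_measurements = sum(estimates$timepoint %in%
                                   c("generation-0", "generation-250")),
    mean_contamination_percent = 100 * mean(contam$B_j),
    n_fixed = sum(dynamics$fixed),
    n_populations = nrow(dynamics),
    significant_strains = vapply(fdr_levels, function(a)
      sum(recs$q_value <= a, na.rm = TRUE), numeric(1)),
    fdr_levels = fdr_levels)

  manifest <- list(
    seed = if (!is.null(study$config)) study$config$seed else NA,
    input_checksum = .checksum(counts),
    stage_rows = c(contamination = nrow(contam),
                   estimates = nrow(estimates),
                   fitness_records = nrow(recs),
                   dynamics = nrow(dynamics)))

  structure(list(contamination = contam, counts_censored = censored,
                 estimates = estimates,
                 fitness = list(records = recs, replicates = repl),
                 dynamics = dynamics, models = models,
                 summary = summary, manifest = manifest),
            class = "bse_run")
}

# strain -> treatment map from the dynamics entries of the sheet
.strain_treatments <- function(sheet, manifest) {
  dyn <- sheet[!(sheet$sample_id %in%
                   c(manifest$sample_0h, manifest$sample_48h)), ]
  map <- character(0)
  for (i in seq_len(nrow(dyn)))
    for (b in dyn$expected_barcodes[[i]])
      map[b] <- dyn$treatment_id[i]
  map
}

# strain -> mean contamination rate over the assay samples containing it
.strain_contamination <- function(contam, sheet, strains) {
  idx <- match(contam$sample_id, sheet$sample_id)
  out <- numeric(length(strains))
  for (k in seq_along(strains)) {
    has <- vapply(sheet$expected_barcodes[idx],
                  function(e) strains[k] %in% e, logical(1))
    out[k] <- mean(contam$B_j[has])
  }
  out
}

.checksum <- function(object) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(object, f)
  unname(tools::md5sum(f))
}

#' Write human-readable result tables for a pipeline run
#'
#' Writes flat TSVs: per-sample contamination, per-strain fitness-change
#' records, strains significant at each FDR level, per-population
#' dynamics, and treatment-contrast tables for the fitness-change and
#' dynamics models.
#'
#' @param run a `bse_run` from [run_pipeline()]
#' @param out_dir output directory (created if needed)
#' @return invisible character vector of files written
#' @export
report <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }
  files <- c(
    wt(run$contamination, "contamination.tsv"),
    wt(run$fitness$records, "fitness_change.tsv"),
    wt(run$dynamics, "dynamics.tsv"))
  for (a in run$summary$fdr_levels) {
    sig <- run$fitness$records[
      !is.na(run$fitness$records$q_value) &
        run$fitness$records$q_value <= a, ]
    files <- c(files, wt(sig, sprintf("significant_strains_fdr%g.tsv", a)))
  }
  if (!is.null(run$models$fitness_change_treatment))
    files <- c(files, wt(tidy_fit(run$models$fitness_change_treatment),
                         "treatment_model.tsv"))
  if (!is.null(run$models$dynamics)) {
    tabs <- lapply(names(run$models$dynamics), function(mn) {
      t <- tidy_fit(run$models$dynamics[[mn]])
      t$metric <- mn
      t
    })
    files <- c(files, wt(do.call(rbind, tabs), "dynamics_models.tsv"))
  }
  invisible(files)
}
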