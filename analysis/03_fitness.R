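#!/usr/bin/env Rscript
# Per-strain fitness: Malthusian/Wrightian estimates from the paired
# pooled assays, fitness change over evolution, replicate rMSE, and
# FDR-controlled per-strain tests.

library(barseqevo)

censored <- read_count_matrix("results/counts_censored.tsv")
sheet <- read_sample_sheet("results/study/sample_sheet.tsv")
manifest <- read.delim("results/study/assay_manifest.tsv",
                       stringsAsFactors = FALSE)

est <- assay_fitness(censored, manifest, sheet)
fc <- fitness_change_records(est)
write.table(fc$records, "results/fitness_change.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(fc$replicates, "results/fitness_change_replicates.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

rmse_g0 <- pooled_rmse(est$w[est$timepoint == "generation-0"],
                       est$strain[est$timepoint == "generation-0"])
rmse_g250 <- pooled_rmse(est$w[est$timepoint == "generation-250"],
                         est$strain[est$timepoint == "generation-250"])
cat(sprintf("replicate fitness rMSE: %.3g (generation 0), %.3g (generation 250)\n",
            rmse_g0, rmse_g250))

for (a in c(0.05, 0.01))
  cat(sprintf("strains with increased fitness at %d%% FDR: %d/%d\n",
              round(100 * a),
              sum(fc$records$q_value <= a, na.rm = TRUE),
              nrow(fc$records)))

truth <- read.delim("results/study/truth_fitness.tsv",
                    stringsAsFactors = FALSE)
m <- merge(fc$records, truth, by = "strain")
ok <- m$median_count > 50
cat(sprintf("estimate vs truth: r = %.3f, MAE = %.4f (n = %d detectable)\n",
            cor(m$delta_w[ok], m$delta_w_truth[ok]),
            mean(abs(m$delta_w[ok] - m$delta_w_truth[ok])), sum(ok)))
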