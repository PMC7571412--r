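#!/usr/bin/env Rscript
# Lineage dynamics: focal-barcode proportion trajectories per population
# and the seven dynamics metrics plus fixation calls.

library(barseqevo)

censored <- read_count_matrix("results/counts_censored.tsv")
sheet <- read_sample_sheet("results/study/sample_sheet.tsv")
populations <- read.delim("results/study/populations.tsv",
                          stringsAsFactors = FALSE)

dyn <- batch_dynamics(censored, populations, sheet)
write.table(dyn, "results/dynamics.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("%d populations summarized; %d fixed (%.0f%%)\n",
            nrow(dyn), sum(dyn$fixed), 100 * mean(dyn$fixed)))
print(tapply(dyn$fixed, dyn$treatment_id, sum))

truth <- read.delim("results/study/truth_dynamics.tsv",
                    stringsAsFactors = FALSE)
truth_fixed <- unique(truth[, c("population_id", "fixed_truth")])
agree <- mean(dyn$fixed[match(truth_fixed$population_id,
                              dyn$population_id)] ==
                truth_fixed$fixed_truth)
cat(sprintf("fixation calls agree with truth for %.0f%% of populations\n",
            100 * agree))
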