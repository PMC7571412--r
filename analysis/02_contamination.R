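#!/usr/bin/env Rscript
# Cross-contamination rates per sample (computed on raw counts, before
# censoring), then censor unexpected barcodes for all downstream stages.

library(barseqevo)

counts <- read_count_matrix("results/study/counts.tsv")
sheet <- read_sample_sheet("results/study/sample_sheet.tsv")
lib <- read_barcode_library("results/study/barcode_library.tsv")

contam <- contamination_report(counts, sheet, lib)
write.table(contam, "results/contamination.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("contamination: mean %.4f%%, median %.4f%% across %d samples\n",
            100 * mean(contam$B_j), 100 * median(contam$B_j),
            nrow(contam)))
cat(sprintf("samples with zero totals excluded: %d\n",
            length(attr(contam, "zero_total_samples"))))

censored <- censor_unexpected(counts, sheet)
write_count_matrix(censored, "results/counts_censored.tsv")
cat(sprintf("censored %d unexpected-cell reads out of %d total\n",
            sum(counts) - sum(censored), sum(counts)))
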