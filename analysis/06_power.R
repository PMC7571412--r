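#!/usr/bin/env Rscript
# Power surfaces for the two designs: per-strain fitness differences
# (t family, noise = replicate rMSE) and treatment-level differences
# (f2 family), over effect size x replication grids.

library(barseqevo)

est <- read.delim("results/fitness_change_replicates.tsv",
                  stringsAsFactors = FALSE)
rmse <- pooled_rmse(est$delta_w, est$strain)
cat(sprintf("replicate fitness-change rMSE used as noise sd: %.4g\n",
            rmse))

surf_t <- power_surface_t(effects = seq(0.005, 0.05, by = 0.005),
                          ns = 2:24, sd = rmse)
write.table(surf_t, "results/power_surface_t.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

surf_f2 <- power_surface_f2(u = 5, vs = seq(10, 150, by = 10),
                            f2s = c(0.02, 0.05, 0.1, 0.15, 0.25, 0.35))
write.table(surf_f2, "results/power_surface_f2.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

n80 <- with(surf_t, tapply(power, fitchange, function(p) {
  nn <- sort(unique(surf_t$n))
  i <- which(p >= 0.8)[1]
  if (is.na(i)) NA else nn[i]
}))
cat("replicates needed for 80% power by fitness effect:\n")
print(n80)
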