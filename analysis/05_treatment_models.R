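#!/usr/bin/env Rscript
# Treatment-level inference: the read-weighted mixed model for fitness
# change (with the contamination covariate and a strain random
# intercept) and the seven dynamics-metric models, all contrasted
# against the standard-condition control (CM diploid, 1:1000).

library(barseqevo)

repl <- read.delim("results/fitness_change_replicates.tsv",
                   stringsAsFactors = FALSE)
recs <- read.delim("results/fitness_change.tsv",
                   stringsAsFactors = FALSE)
truth <- read.delim("results/study/truth_fitness.tsv",
                    stringsAsFactors = FALSE)
contam <- read.delim("results/contamination.tsv",
                     stringsAsFactors = FALSE)
dyn <- read.delim("results/dynamics.tsv", stringsAsFactors = FALSE)

repl$treatment_id <- truth$treatment_id[match(repl$strain, truth$strain)]
# per-strain contamination covariate: mean rate over that strain's
# population samples
pop_of <- truth$population_id[match(repl$strain, truth$strain)]
contam$pop <- sub("^dyn_(pop[0-9]+)_.*$", "\\1", contam$sample_id)
mean_b <- tapply(contam$B_j, contam$pop, mean)
repl$contamination <- as.numeric(mean_b[pop_of])

dat <- repl[repl$weight > 0, ]
fit <- fit_treatment_model(data.frame(
  delta_w = dat$delta_w, treatment_id = dat$treatment_id,
  contamination = dat$contamination, strain = dat$strain,
  weight = dat$weight))
tab <- tidy_fit(fit)
write.table(tab, "results/treatment_model.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("fitness change ~ treatment (+ contamination) + (1 | strain):\n")
print(tab, row.names = FALSE)
if (!is.null(fit$dropped))
  cat("covariate dropped as non-significant:", fit$dropped, "\n")

dyn_fits <- fit_dynamics_models(dyn)
dyn_tab <- do.call(rbind, lapply(names(dyn_fits), function(mn) {
  t <- tidy_fit(dyn_fits[[mn]]); t$metric <- mn; t
}))
write.table(dyn_tab, "results/dynamics_models.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- dyn_tab[grepl("^treatment", dyn_tab$term) & dyn_tab$p_value < 0.05, ]
cat(sprintf("\ndynamics ~ treatment: %d significant treatment contrasts\n",
            nrow(sig)))
print(sig[, c("metric", "term", "estimate", "p_value", "signif")],
      row.names = FALSE)
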