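#!/usr/bin/env Rscript
# Precision of Mantel scores as a function of sample size.
#
# For each connectivity level, 100 replicate studies draw 10 / 50 / 100 /
# 1000 / 2500 / 5000 individuals at random from the whole breeding range
# (N = 10,000). The per-cell SD of the replicate scores measures precision;
# the headline findings are the large SD at the smallest samples (weakest
# connectivity worst) and the collapse of the SD once 10% or more of the
# population is sampled.

library(mantelmc)

cfg <- sample_size_experiment_config(master_seed = 1L)
records <- run_sample_size_experiment(cfg)
summary <- summarize_replicates(records)
summary$size <- as.integer(summary$design_level)
summary <- summary[order(summary$connectivity, summary$size), ]

dir.create(file.path("results", "sample_size"), recursive = TRUE,
           showWarnings = FALSE)
write.csv(records, file.path("results", "sample_size", "results.csv"),
          row.names = FALSE)
write.csv(summary, file.path("results", "sample_size", "summary.csv"),
          row.names = FALSE)

worst <- summary[summary$size == 10, ]
message("SD of replicate scores at sample size 10:")
for (i in seq_len(nrow(worst))) {
  message(sprintf("  %-6s: %.3f", worst$connectivity[i], worst$sd_r[i]))
}
big <- summary[summary$size >= 1000, ]
message(sprintf("max SD at sizes >= 1000 (all levels): %.4f", max(big$sd_r)))
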