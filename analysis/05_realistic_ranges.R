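#!/usr/bin/env Rscript
# Realistic spatially clustered populations over the bundled synthetic
# ranges (wide / compact / elongated), sampled from k of 20 top-density
# sites.
#
# Populations of 10,000 individuals per range are generated from Gaussian
# random fields (autocorrelation range 10 cells, magnitude 100) and linked
# by longitudinal-rank matching at three bandwidths (2% / 26% / 50% of the
# population, the study's proportions). Each replicate study marks 200
# individuals across k sites drawn from the 20 highest-density grid cells,
# k = 3..20, 100 replicates per cell, recording the mean distance between
# selected site centroids. Expected pattern: highly variable estimates at
# small k, with underestimation when sites are close together and
# overestimation when far apart.

library(mantelmc)

n <- 10000L
cfg <- realistic_experiment_config(
  n = n,
  bandwidths = c(high = round(0.02 * n), medium = round(0.26 * n),
                 low = round(0.50 * n)),
  master_seed = 1L)
records <- run_realistic_experiment(cfg)
summary <- summarize_replicates(records)

out <- file.path("results", "realistic")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
write.csv(records, file.path(out, "results.csv"), row.names = FALSE)
write.csv(summary, file.path(out, "summary.csv"), row.names = FALSE)

for (fx in unique(records$design_level)) {
  sub <- records[records$design_level == fx, ]
  v3 <- tapply(sub$r_sample[sub$k_sites == 3], sub$connectivity[sub$k_sites == 3], sd)
  v20 <- tapply(sub$r_sample[sub$k_sites == 20], sub$connectivity[sub$k_sites == 20], sd)
  few <- sub[sub$k_sites <= 5, ]
  message(sprintf(
    "%-10s SD(r) k=3: %s | k=20: %s | cor(bias, site distance) k<=5: %.2f",
    fx, paste(sprintf("%.3f", v3), collapse = "/"),
    paste(sprintf("%.3f", v20), collapse = "/"),
    cor(few$bias_global, few$site_centroid_mean_dist)))
}
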