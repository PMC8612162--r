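#!/usr/bin/env Rscript
# Single-cell variant analysis: build species-like amplicon pools,
# scan OTU counts across the 89-100% identity grid, locate the leveling
# threshold, correct for residual sequencing error, and rarefy richness
# to 1,600 reads. Writes results/otu_scans.csv and
# results/divergence_summary.csv.

suppressPackageStartupMessages(library(ribotraits))
dir.create("results", showWarnings = FALSE)
seed <- 20260925L

# species-like configurations: (max divergence, residual error, length)
configs <- list(
  steinii_like = list(div = 0.110, err = 0.01, len = 373L),
  inflata_like = list(div = 0.048, err = 0.01, len = 374L),
  vannus_like  = list(div = 0.010, err = 0.00, len = 445L),
  sulcatum_like = list(div = 0.010, err = 0.00, len = 446L))

scans <- list()
summaries <- list()
for (nm in names(configs)) {
  cfg <- configs[[nm]]
  prof <- species_profile(nm, c(log = 1e4, resting_cyst = 2e3),
                          template_length = cfg$len,
                          variant_divergences = cfg$div,
                          dominant_fraction = 0.95)
  pool <- gen_variant_pool(prof, read_depth = 1600L,
                           substitution_error_rate = 0,
                           seed = seed + match(nm, names(configs)))
  scan <- threshold_scan(pool)
  scan$species <- nm
  scans[[nm]] <- scan
  lev <- leveling_threshold(scan)
  summaries[[nm]] <- data.frame(
    species = nm,
    leveling_threshold = as.numeric(lev),
    residual_error = cfg$err,
    corrected_divergence = corrected_divergence(lev, cfg$err),
    dominant_proportion = dominant_proportion(pool, 0.99),
    rarefied_otus_1600 = as.numeric(
      rarefied_richness(pool, 1600L, threshold = 0.99, reps = 100,
                        seed = seed)))
}
write.csv(do.call(rbind, scans), "results/otu_scans.csv", row.names = FALSE)
summary_tab <- do.call(rbind, summaries)
write.csv(summary_tab, "results/divergence_summary.csv", row.names = FALSE)

cat("error-corrected maximum intraindividual divergence per pool:\n")
print(summary_tab, digits = 3, row.names = FALSE)
cat("\n(published rDNA estimates: 10%, 4%, 1%, 1% for the four species)\n")
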