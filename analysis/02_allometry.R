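#!/usr/bin/env Rscript
# Fit the allometric scaling relations on the simulated cells and verify
# the exact algebraic identities among parameterizations: the ESD slope
# is 3x the CV slope, the population lift leaves coefficients unchanged,
# and the ratio of the two population relations gives the resting-cyst
# estimator baseline (0.33, 3.034; 10^3.034 ~ 1081).
# Reads results/cells.csv; writes results/allometry_fits.json.

suppressPackageStartupMessages(library(ribotraits))
cells <- read_trait_table("results/cells.csv")
veg <- cells[cells$stage != "resting_cyst", ]

fits <- list(
  rdna_cv = fit_power_law(cells$cell_volume, cells$rdna_cnpc,
                          "rDNA_CNPC", "CV"),
  rrna_cv_veg = fit_power_law(veg$cell_volume, veg$rrna_cnpc,
                              "rRNA_CNPC", "CV"),
  mv_cv = fit_power_law(cells$cell_volume, cells$macronuclear_volume,
                        "MV", "CV"))
fits$rdna_esd <- cv_fit_to_esd_fit(fits$rdna_cv)
fits$rrna_esd_veg <- cv_fit_to_esd_fit(fits$rrna_cv_veg)
fits$ratio_esd <- ratio_fit(percell_to_population(fits$rrna_esd_veg),
                            percell_to_population(fits$rdna_esd))
write_fit_json(fits, "results/allometry_fits.json")

cat("refitted exponents (generating values 0.76, 0.87, 0.83):\n")
cat(sprintf("  rDNA ~ CV^%.3f  (R2 = %.2f)\n",
            fits$rdna_cv$slope, fits$rdna_cv$r_squared))
cat(sprintf("  rRNA ~ CV^%.3f  (R2 = %.2f, resting cysts excluded)\n",
            fits$rrna_cv_veg$slope, fits$rrna_cv_veg$r_squared))
cat(sprintf("  MV   ~ CV^%.3f  (R2 = %.2f)\n",
            fits$mv_cv$slope, fits$mv_cv$r_squared))
cat(sprintf("ESD-basis identities: rDNA slope %.3f = 3 x %.3f\n",
            fits$rdna_esd$slope, fits$rdna_cv$slope))
reg_baseline <- ratio_fit(allometry_registry()$rrna_total_esd,
                          allometry_registry()$rdna_total_esd)
cat(sprintf("published baseline: ratio ~ %d * ESD^%.2f; refit here: %.0f * ESD^%.2f\n",
            round(10^reg_baseline$intercept), reg_baseline$slope,
            10^fits$ratio_esd$intercept, fits$ratio_esd$slope))
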