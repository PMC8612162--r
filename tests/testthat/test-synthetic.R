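# Synthetic-data generators: determinism and fidelity to the generating
# models.

test_that("all generators are deterministic under a fixed seed", {
  prof <- colpoda_profiles(18)$steinii
  expect_identical(gen_cells(prof, 5, 0.25, seed = 3),
                   gen_cells(prof, 5, 0.25, seed = 3))
  p1 <- gen_population(prof, 50, 0.4, 20, 0.1, seed = 4)
  p2 <- gen_population(prof, 50, 0.4, 20, 0.1, seed = 4)
  expect_identical(unclass(p1)[], unclass(p2)[])
  expect_identical(gen_dilution_series(1, 5, 0.1, seed = 5),
                   gen_dilution_series(1, 5, 0.1, seed = 5))
  v1 <- gen_variant_pool(prof, seed = 6, substitution_error_rate = 0.01)
  v2 <- gen_variant_pool(prof, seed = 6, substitution_error_rate = 0.01)
  expect_identical(v1$variants, v2$variants)
  expect_identical(gen_growth_dataset(noise_sd = 0.1, seed = 7),
                   gen_growth_dataset(noise_sd = 0.1, seed = 7))
  # and different seeds differ
  expect_false(identical(gen_cells(prof, 5, 0.25, seed = 3),
                         gen_cells(prof, 5, 0.25, seed = 8)))
})

test_that("seeded generators do not disturb the caller's RNG stream", {
  prof <- colpoda_profiles(18)$steinii
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(gen_cells(prof, 3, seed = 99))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("zero-noise cell tables lie exactly on the generating power laws", {
  prof <- colpoda_profiles(18)$steinii
  cells <- gen_cells(prof, n_per_stage = 6, noise_sd_log10 = 0, seed = 21)
  veg <- cells[cells$stage != "resting_cyst", ]
  rdna_fit <- fit_power_law(cells$cell_volume, cells$rdna_cnpc,
                            "rDNA_CNPC", "CV")
  expect_equal(rdna_fit$slope, prof$rdna_fit$slope)
  expect_equal(rdna_fit$intercept, prof$rdna_fit$intercept)
  expect_equal(rdna_fit$r_squared, 1.0)
  rrna_fit <- fit_power_law(veg$cell_volume, veg$rrna_cnpc,
                            "rRNA_CNPC", "CV")
  expect_equal(rrna_fit$slope, prof$rrna_fit$slope)
  expect_equal(rrna_fit$intercept, prof$rrna_fit$intercept)
  mv_fit <- fit_power_law(cells$cell_volume, cells$macronuclear_volume,
                          "MV", "CV")
  expect_equal(mv_fit$slope, prof$mv_exponent)
})

test_that("cyst rRNA collapse matches the observed stage means", {
  # the large species at 18 degC: log-phase vs resting-cyst per-cell rRNA
  # contrast of ~4200x (1.3e8 vs 3.1e4 copies)
  prof <- colpoda_profiles(18)$inflata
  cells <- gen_cells(prof, n_per_stage = 20, noise_sd_log10 = 0, seed = 31)
  log_rrna <- mean(cells$rrna_cnpc[cells$stage == "log"])
  cyst_rrna <- mean(cells$rrna_cnpc[cells$stage == "resting_cyst"])
  contrast <- log_rrna / cyst_rrna
  expect_gt(contrast, 2000)
  expect_lt(contrast, 5000)
  expect_equal(log_rrna, 1.3e8, tolerance = 0.25)
  expect_equal(cyst_rrna, 3.1e4, tolerance = 0.35)
  # vegetative-vs-cyst contrast also in the published 200-5000x band for
  # the small species
  prof_s <- colpoda_profiles(18)$steinii
  cells_s <- gen_cells(prof_s, 20, 0, seed = 32)
  contrast_s <- mean(cells_s$rrna_cnpc[cells_s$stage == "log"]) /
    mean(cells_s$rrna_cnpc[cells_s$stage == "resting_cyst"])
  expect_gt(contrast_s, 200)
  expect_lt(contrast_s, 5000)
})

test_that("population sweep recovers the cyst fraction within the suppression", {
  prof <- colpoda_profiles(18)$steinii
  errs <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    pool <- gen_population(prof, 200, f, 20, 0, seed = 13)
    abs(as.numeric(cyst_fraction(pool)) - attr(pool, "true_fraction"))
  }, numeric(1))
  expect_lte(max(errs), prof$cyst_rrna_suppression + 1e-12)
})

test_that("dilution-series generator respects its contracts", {
  s <- gen_dilution_series(1.0, 5, 0, seed = 1, n_replicates = 1)
  expect_equal(nrow(s), 5L)
  expect_equal(fit_standard_curve(s$log10_copies, s$ct)$slope,
               -1 / log10(2))
  expect_error(gen_dilution_series(1.5), "0.8, 1.2")
  expect_error(gen_dilution_series(1.0, 0), "decade")
  # too-short series exercises the insufficient-data path downstream
  short <- gen_dilution_series(1.0, 2, 0, seed = 1, n_replicates = 1)
  expect_error(fit_standard_curve(short$log10_copies, short$ct), ">= 3")
})

test_that("variant-pool generator builds the requested structure", {
  prof <- make_profile(divergences = c(0.11), dominant = 0.95)
  pool <- gen_variant_pool(prof, read_depth = 1600, seed = 9)
  expect_equal(sum(pool$variants$count), 1600L)
  expect_equal(nrow(pool$variants), 2L)
  expect_equal(max(pool$variants$count), 1520L)  # 95% of 1600
  # no minor variants: single-variant pool
  mono <- gen_variant_pool(make_profile(dominant = 1), seed = 9)
  expect_equal(nrow(mono$variants), 1L)
  expect_equal(dominant_proportion(mono, 0.99), 1.0)
  # substitution errors create singletons and are recorded in the pool
  noisy <- gen_variant_pool(prof, read_depth = 1600,
                            substitution_error_rate = 0.01, seed = 10)
  expect_equal(noisy$residual_error_rate, 0.01)
  expect_equal(sum(noisy$variants$count), 1600L)
  expect_gt(sum(noisy$variants$count == 1L), 0)
})

test_that("growth-dataset generator reproduces registry truths exactly", {
  dat <- gen_growth_dataset(0.057, 0.229, -2.746, noise_sd = 0)
  fit <- fit_growth_model(dat$r, dat$t, dat$x, "rRNA_CNPC")
  expect_equal(fit$coef_x, 0.229, tolerance = 1e-12)
  dat16 <- gen_growth_dataset(0.055, 0.206, -1.92, noise_sd = 0)
  expect_equal(fit_growth_model(dat16$r, dat16$t, dat16$x, "CV")$coef_x,
               0.206, tolerance = 1e-12)
})
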