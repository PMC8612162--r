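# Power-law fitting and the algebraic transformations among
# parameterizations.

test_that("fit_power_law recovers generating coefficients exactly on noise-free data", {
  x <- 10^seq(3, 5.5, length.out = 20)
  y <- 10^0.61 * x^0.76
  fit <- fit_power_law(x, y, "rDNA_CNPC", "CV")
  expect_equal(fit$slope, 0.76)
  expect_equal(fit$intercept, 0.61)
  expect_equal(fit$r_squared, 1.0)
  # MV ~ CV^0.83
  mv <- 10^(-0.84) * x^0.83
  expect_equal(fit_power_law(x, mv, "MV", "CV")$slope, 0.83)
})

test_that("fit_power_law handles degenerate and invalid input", {
  x <- c(1, 10, 100, 1000)
  fit <- fit_power_law(x, rep(5, 4))
  expect_equal(fit$slope, 0)
  expect_equal(fit$r_squared, 0)
  expect_error(fit_power_law(c(1, -2, 3), c(1, 2, 3)), "rows 2")
  expect_error(fit_power_law(c(1, 2), c(1, 2)), "n >= 3")
})

test_that("CV-to-ESD transform triples the slope and shifts the intercept by a*log10(pi/6)", {
  reg <- allometry_registry()
  esd_fit <- cv_fit_to_esd_fit(reg$rdna_cv)
  expect_equal(esd_fit$slope, 2.28)
  # exact transform gives 0.398...; the published ESD relation was refit
  # independently and prints 0.396
  expect_equal(esd_fit$intercept, 0.61 + 0.76 * log10(pi / 6))
  expect_equal(esd_fit$intercept, 0.396, tolerance = 0.003)
  rrna_esd <- cv_fit_to_esd_fit(reg$rrna_cv_veg)
  expect_equal(rrna_esd$slope, 3 * 0.87)
  expect_equal(rrna_esd$slope, 2.61)
  # zero slope: intercept unchanged
  flat <- power_law_fit(0, 1.5, predictor = "CV")
  expect_equal(cv_fit_to_esd_fit(flat)$intercept, 1.5)
  expect_error(cv_fit_to_esd_fit(esd_fit), "must be 'CV'")
})

test_that("transforming data then fitting equals fitting transformed data", {
  set.seed(42)
  cv <- 10^runif(50, 3, 5.5)
  y <- 10^(0.61 + 0.76 * log10(cv) + rnorm(50, 0, 0.2))
  fit_cv <- fit_power_law(cv, y, "rDNA_CNPC", "CV")
  fit_esd_direct <- fit_power_law(esd_from_volume(cv), y, "rDNA_CNPC", "ESD")
  fit_esd_transformed <- cv_fit_to_esd_fit(fit_cv)
  expect_equal(fit_esd_transformed$slope, fit_esd_direct$slope)
  expect_equal(fit_esd_transformed$intercept, fit_esd_direct$intercept)
})

test_that("per-cell to population lifting adds the N term once and relabels", {
  reg <- allometry_registry()
  pop <- percell_to_population(reg$rdna_esd)
  expect_true(pop$population)
  expect_equal(pop$slope, reg$rdna_esd$slope)
  expect_equal(pop$intercept, reg$rdna_esd$intercept)
  expect_equal(pop$response, "rDNA_total")
  expect_error(percell_to_population(pop), "already population-level")
})

test_that("ratio of the population relations yields the cyst-estimator baseline", {
  reg <- allometry_registry()
  r <- ratio_fit(reg$rrna_total_esd, reg$rdna_total_esd)
  expect_equal(r$slope, 0.33)
  expect_equal(r$intercept, 3.034)
  expect_false(r$population)  # N cancels
  expect_equal(round(10^r$intercept), 1081)
  # a fit minus itself is identically 1
  self <- ratio_fit(reg$rdna_esd, reg$rdna_esd)
  expect_equal(self$slope, 0)
  expect_equal(self$intercept, 0)
  # MV-based per-cell ratio from the published coefficients
  mv_ratio <- ratio_fit(reg$rrna_mv_veg, reg$rdna_mv)
  expect_equal(mv_ratio$slope, 0.15)
  expect_equal(mv_ratio$intercept, 3.03)
  expect_error(ratio_fit(reg$rrna_total_esd, reg$rdna_cv), "predictor")
  expect_error(ratio_fit(reg$rrna_total_esd, reg$rdna_esd), "mixed")
})

test_that("predict evaluates the power law, with N only for population fits", {
  reg <- allometry_registry()
  expect_equal(predict(reg$rdna_cv, 1e4), 10^(0.61 + 0.76 * 4))
  expect_equal(predict(reg$rdna_cv, 1e4), 4466.836, tolerance = 1e-6)
  expect_equal(predict(reg$rdna_cv, 1), 10^0.61)
  expect_equal(predict(reg$rdna_total_esd, 20, n = 1000),
               1000 * 10^(0.396 + 2.28 * log10(20)))
  expect_error(predict(reg$rdna_total_esd, 20), "requires n")
  expect_error(predict(reg$rdna_cv, 20, n = 5), "per-cell")
  expect_error(predict(reg$rdna_cv, -3), "> 0")
})

test_that("registry stores the published coefficients verbatim", {
  reg <- allometry_registry()
  expect_equal(reg$rdna_cv$slope, 0.76)
  expect_equal(reg$rdna_cv$r_squared, 0.91)
  expect_equal(reg$rdna_cv$n, 20L)
  expect_equal(reg$rrna_cv_veg$slope, 0.87)
  expect_equal(reg$rrna_cv_veg$intercept, 3.67)
  expect_equal(reg$rrna_cv_veg$r_squared, 0.84)
  expect_equal(reg$rrna_cv_veg$n, 16L)
  expect_equal(reg$rdna_mv$slope, 0.90)
  expect_equal(reg$rdna_mv$intercept, 1.44)
  expect_true(reg$rdna_total_esd$population)
  expect_true(reg$rrna_total_esd$population)
})

test_that("exponent recovery under log-normal noise hits the stated reliability", {
  # truth 0.87, log10 residual sd 0.25, n = 200 per replicate; the fitted
  # exponent should land within +/-0.05 in at least 95% of 100 replicates
  hits <- logical(100)
  for (i in 1:100) {
    set.seed(7000 + i)
    cv <- 10^runif(200, 1.3, 5.3)
    rrna <- 10^(3.67 + 0.87 * log10(cv) + rnorm(200, 0, 0.25))
    fit <- fit_power_law(cv, rrna, "rRNA_CNPC", "CV")
    hits[i] <- abs(fit$slope - 0.87) <= 0.05
  }
  expect_gte(mean(hits), 0.95)
})

test_that("composed MV and ESD scalings predict the published N/C exponent", {
  # MV ~ CV^0.83 implies MV/CV ~ CV^-0.17 ~ ESD^-0.51, near the
  # independently fitted ESD^-0.522
  mv_cv <- power_law_fit(0.83, -0.84, "MV", "CV")
  nc_cv <- ratio_fit(mv_cv, power_law_fit(1, 0, "CV", "CV"))
  nc_esd <- cv_fit_to_esd_fit(nc_cv)
  expect_equal(nc_esd$slope, -0.51)
  expect_lt(abs(nc_esd$slope - (-0.522)), 0.02)
})
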