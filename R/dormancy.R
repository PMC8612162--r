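# Resting-cyst fraction estimation from population rRNA/rDNA totals.
#
# Vegetative cells obey a size-dependent total rRNA:rDNA copy-number ratio
# (~1081 * ESD^0.33 for Colpoda); resting cysts carry near-vegetative rDNA
# but orders of magnitude less rRNA, so a deficit in the measured ratio
# relative to the size expectation estimates the cyst share of the rDNA
# pool.

#' Construct a population pool
#'
#' Population-level totals used by the resting-cyst estimator.
#'
#' @param esd Vegetative-cell equivalent spherical diameter, um.
#' @param rdna_total,rrna_total Total 18S rDNA / rRNA copies in the
#'   population (e.g. from qPCR), >= 0.
#' @param n_cells Optional cell abundance.
#' @param rrna_rc Total rRNA copies residing in resting cysts (default 0;
#'   negligible in practice, ~0.02-0.5% of a vegetative cell's content).
#' @param rdna_rc Optional total rDNA copies residing in resting cysts.
#' @return An object of class `population_pool`.
#' @export
population_pool <- function(esd, rdna_total, rrna_total,
                            n_cells = NA_real_, rrna_rc = 0,
                            rdna_rc = NA_real_) {
  if (!is.finite(esd) || esd <= 0) stop("population_pool(): esd must be > 0")
  if (rdna_total < 0 || rrna_total < 0 || rrna_rc < 0) {
    stop("population_pool(): totals must be >= 0")
  }
  structure(list(esd = esd, rdna_total = rdna_total,
                 rrna_total = rrna_total, n_cells = n_cells,
                 rrna_rc = rrna_rc, rdna_rc = rdna_rc),
            class = "population_pool")
}

#' @export
print.population_pool <- function(x, ...) {
  cat(sprintf(
    "<population_pool> ESD %.3g um, rDNA %.3g, rRNA %.3g copies%s\n",
    x$esd, x$rdna_total, x$rrna_total,
    if (is.na(x$n_cells)) "" else sprintf(", N = %g", x$n_cells)))
  invisible(x)
}

#' Size-expected rRNA:rDNA copy-number ratio of an all-vegetative population
#'
#' Evaluates the baseline ratio relation at the given cell size; with the
#' default Colpoda-derived baseline this is 10^3.034 * ESD^0.33
#' (~1081 * ESD^0.33).
#'
#' @param esd Equivalent spherical diameter, um.
#' @param baseline A [power_law_fit()] for the ratio; defaults to the
#'   registry relation `rrna_rdna_ratio_esd`.
#' @return Expected total rRNA / total rDNA ratio (dimensionless).
#' @export
expected_ratio <- function(esd, baseline = NULL) {
  if (is.null(baseline)) baseline <- allometry_registry()$rrna_rdna_ratio_esd
  stopifnot(inherits(baseline, "power_law_fit"))
  if (any(esd <= 0)) stop("expected_ratio(): esd must be > 0")
  predict(baseline, esd)
}

#' Estimate the resting-cyst fraction of a population's rDNA pool
#'
#' cyst_fraction = 1 - ((rRNA_total - rRNA_rc) / rDNA_total) /
#' (10^b * ESD^a), with (a, b) taken from the baseline ratio relation
#' (defaults a = 0.33, b = 3.034, i.e. the constant ~1081). A ratio equal
#' to the size expectation gives 0 (all vegetative); a vanished rRNA pool
#' gives 1 (all resting cysts). Measurement noise can push the raw value
#' outside [0, 1]; it is clamped with the raw value kept in the `"raw"`
#' attribute and `"flag"` set.
#'
#' @param pool A [population_pool()] (requires rdna_total > 0).
#' @param baseline Ratio baseline as in [expected_ratio()].
#' @return Estimated cyst fraction in [0, 1], with attributes `"raw"` and
#'   (when clamped) `"flag"`.
#' @export
cyst_fraction <- function(pool, baseline = NULL) {
  stopifnot(inherits(pool, "population_pool"))
  if (pool$rdna_total <= 0) {
    stop("cyst_fraction(): undefined for rdna_total = 0")
  }
  effective_rrna <- pool$rrna_total - pool$rrna_rc
  if (effective_rrna < 0) {
    stop("cyst_fraction(): rrna_rc exceeds rrna_total")
  }
  ratio <- effective_rrna / pool$rdna_total
  raw <- 1 - ratio / expected_ratio(pool$esd, baseline)
  est <- min(max(raw, 0), 1)
  attr(est, "raw") <- raw
  if (raw < 0 || raw > 1) attr(est, "flag") <- "clamped"
  est
}

#' Percentile bootstrap interval for the cyst-fraction estimate
#'
#' Resamples replicate population pools with replacement, averages the
#' per-pool estimates within each resample, and returns percentile
#' quantiles. Deterministic under a fixed seed.
#'
#' @param pools List of >= 3 [population_pool()] replicates.
#' @param baseline Ratio baseline as in [expected_ratio()].
#' @param reps Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return List with `estimate` (mean of per-replicate estimates),
#'   `lower`, `upper`, `conf`, `reps`.
#' @export
cyst_fraction_ci <- function(pools, baseline = NULL, reps = 1000L,
                             seed = NULL, conf = 0.95) {
  if (!is.list(pools) || length(pools) < 3L) {
    stop("cyst_fraction_ci(): need >= 3 replicate pools")
  }
  ests <- vapply(pools, function(p) as.numeric(cyst_fraction(p, baseline)),
                 numeric(1))
  boot_means <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      mean(ests[sample.int(length(ests), replace = TRUE)])
    }, numeric(1))
  })
  qs <- stats::quantile(boot_means, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  list(estimate = mean(ests), lower = qs[1], upper = qs[2],
       conf = conf, reps = as.integer(reps))
}
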