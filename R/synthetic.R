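# Seeded generators emulating the statistical structure of single-cell
# trait tables, mixed vegetative/cyst populations, qPCR dilution series,
# denoised amplicon variant pools, and growth-rate data sets.

#' Construct a species simulation profile
#'
#' Encodes one species' per-stage cell-size distribution, the generating
#' copy-number power laws, the resting-cyst rRNA suppression, and the
#' amplicon-pool structure.
#'
#' @param name Species label.
#' @param stage_cv_means Named vector of geometric-mean cell volumes
#'   (um^3) per stage; names drawn from [LIFE_STAGES].
#' @param cv_log10_sd Log10 SD of cell volume within a stage (log-normal
#'   scatter).
#' @param rdna_fit,rrna_fit Generating [power_law_fit()]s for per-cell
#'   rDNA / rRNA copies vs CV (defaults: the registry CV-based relations).
#' @param cyst_rrna_suppression Multiplicative factor applied to the
#'   size-expected rRNA of resting cysts, in (0, 1); order 1e-2 to 1e-4.
#' @param mv_exponent MV ~ CV^exponent scaling (default 0.83).
#' @param mv_log10_intercept log10 intercept of the MV relation; default
#'   -0.84 puts MV/CV near 3% at CV = 1e4 um^3, inside the observed 1-8%
#'   band.
#' @param template_length Amplicon template length, nt (default 373,
#'   a V4-like fragment).
#' @param variant_divergences Divergence fractions of minor variants from
#'   the template, each in (0, 0.15].
#' @param dominant_fraction Read fraction of the dominant variant.
#' @return An object of class `species_profile`.
#' @export
species_profile <- function(name,
                            stage_cv_means,
                            cv_log10_sd = 0.1,
                            rdna_fit = NULL,
                            rrna_fit = NULL,
                            cyst_rrna_suppression = 1e-2,
                            mv_exponent = 0.83,
                            mv_log10_intercept = -0.84,
                            template_length = 373L,
                            variant_divergences = numeric(0),
                            dominant_fraction = 0.95) {
  if (is.null(rdna_fit)) rdna_fit <- allometry_registry()$rdna_cv
  if (is.null(rrna_fit)) rrna_fit <- allometry_registry()$rrna_cv_veg
  stopifnot(inherits(rdna_fit, "power_law_fit"),
            inherits(rrna_fit, "power_law_fit"),
            all(names(stage_cv_means) %in% LIFE_STAGES),
            all(stage_cv_means > 0),
            cyst_rrna_suppression > 0, cyst_rrna_suppression < 1,
            all(variant_divergences > 0), all(variant_divergences <= 0.15),
            dominant_fraction > 0, dominant_fraction <= 1)
  structure(list(name = name, stage_cv_means = stage_cv_means,
                 cv_log10_sd = cv_log10_sd, rdna_fit = rdna_fit,
                 rrna_fit = rrna_fit,
                 cyst_rrna_suppression = cyst_rrna_suppression,
                 mv_exponent = mv_exponent,
                 mv_log10_intercept = mv_log10_intercept,
                 template_length = as.integer(template_length),
                 variant_divergences = variant_divergences,
                 dominant_fraction = dominant_fraction),
            class = "species_profile")
}

#' Default Colpoda profiles
#'
#' Profiles for the small (C. steinii-like) and large (C. inflata-like)
#' soil species, parameterized from the published per-stage means at the
#' given temperature. Stage cell volumes follow the printed values and
#' reduction percentages; the cyst rRNA suppression factors reproduce the
#' measured resting-cyst rRNA contents (3.4e4 and 3.1e4 copies at 18
#' degrees C) relative to the size-expected values, giving the observed
#' 200-5000x vegetative:cyst rRNA contrasts.
#'
#' @param temperature 18 or 28 (degrees C).
#' @return Named list of two [species_profile()]s: `steinii`, `inflata`.
#' @export
colpoda_profiles <- function(temperature = 18) {
  stopifnot(temperature %in% c(18, 28))
  if (temperature == 18) {
    steinii_cv <- c(lag = 1.28e4, log = 1.1e4, plateau = 6.0e3,
                    unstable_cyst = 5.3e3, resting_cyst = 2.0e3)
    inflata_cv <- c(lag = 2.14e5, log = 1.2e5, plateau = 6.5e4,
                    unstable_cyst = 2.1e4, resting_cyst = 2.0e4)
  } else {
    steinii_cv <- c(lag = 8.0e3, log = 6.5e3, plateau = 4.5e3,
                    unstable_cyst = 4.0e3, resting_cyst = 2.0e3)
    inflata_cv <- c(lag = 1.4e5, log = 8.0e4, plateau = 4.5e4,
                    unstable_cyst = 1.6e4, resting_cyst = 1.5e4)
  }
  list(
    steinii = species_profile(
      "Colpoda_steinii", steinii_cv,
      cyst_rrna_suppression = 9.8e-3,
      template_length = 373L,
      variant_divergences = c(0.11),
      dominant_fraction = 0.95),
    inflata = species_profile(
      "Colpoda_inflata", inflata_cv,
      cyst_rrna_suppression = 1.2e-3,
      template_length = 374L,
      variant_divergences = c(0.05),
      dominant_fraction = 0.95)
  )
}

#' Generate a single-cell trait + ribotype table
#'
#' Per stage: cell volumes are log-normal around the profile's stage
#' mean; MV, rDNA and rRNA follow the generating power laws with
#' multiplicative log-normal noise (log10 residual SD `noise_sd_log10`);
#' resting-cyst rRNA is additionally multiplied by the profile's
#' suppression factor. With zero noise (and `cv_log10_sd = 0` left as
#' scatter only in CV), points lie exactly on the generating laws, so
#' refitting recovers the coefficients exactly.
#'
#' @param profile A [species_profile()].
#' @param n_per_stage Cells per stage (default 5).
#' @param noise_sd_log10 Log10 residual SD (default 0.25, matching the
#'   R2 ~ 0.84-0.93 bands of the observed fits).
#' @param temperature Recorded temperature, degrees C.
#' @param seed Integer seed; same seed, same table.
#' @return data.frame: species, stage, temperature, replicate,
#'   cell_volume, esd, macronuclear_volume, rdna_cnpc, rrna_cnpc.
#' @export
gen_cells <- function(profile, n_per_stage = 5L, noise_sd_log10 = 0.25,
                      temperature = 18, seed = NULL) {
  stopifnot(inherits(profile, "species_profile"), n_per_stage >= 1L)
  stages <- names(profile$stage_cv_means)
  with_seed(seed, {
    rows <- lapply(stages, function(st) {
      cv <- 10^(log10(profile$stage_cv_means[[st]]) +
                  stats::rnorm(n_per_stage, 0, profile$cv_log10_sd))
      mv <- 10^(profile$mv_log10_intercept +
                  profile$mv_exponent * log10(cv) +
                  stats::rnorm(n_per_stage, 0, noise_sd_log10))
      rdna <- predict(profile$rdna_fit, cv) *
        10^stats::rnorm(n_per_stage, 0, noise_sd_log10)
      rrna <- predict(profile$rrna_fit, cv) *
        10^stats::rnorm(n_per_stage, 0, noise_sd_log10)
      if (st == "resting_cyst") rrna <- rrna * profile$cyst_rrna_suppression
      data.frame(species = profile$name, stage = st,
                 temperature = temperature,
                 replicate = seq_len(n_per_stage),
                 cell_volume = cv, esd = esd_from_volume(cv),
                 macronuclear_volume = mv,
                 rdna_cnpc = rdna, rrna_cnpc = rrna,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a mixed vegetative/resting-cyst population pool
#'
#' Builds a population of `n_cells` cells of common size `esd`, a known
#' fraction of which are resting cysts. Vegetative per-cell rDNA and rRNA
#' follow the published ESD-based relations (10^0.396 * ESD^2.28 and
#' 10^3.43 * ESD^2.61), whose ratio is the estimator baseline
#' 10^3.034 * ESD^0.33; cysts carry the same per-cell rDNA but rRNA
#' suppressed by the profile factor. Totals are summed with optional
#' multiplicative log-normal noise per cell.
#'
#' @param profile A [species_profile()] (supplies the suppression factor).
#' @param n_cells Number of cells.
#' @param cyst_fraction True resting-cyst fraction in [0, 1]; realised as
#'   `round(cyst_fraction * n_cells)` cysts.
#' @param esd Common cell ESD, um.
#' @param noise_sd_log10 Per-cell log10 noise SD (default 0).
#' @param seed Integer seed.
#' @return A [population_pool()] with attributes `"true_fraction"` (the
#'   realised cyst fraction) and `"suppression"`.
#' @export
gen_population <- function(profile, n_cells = 100L, cyst_fraction = 0,
                           esd = 20, noise_sd_log10 = 0, seed = NULL) {
  stopifnot(inherits(profile, "species_profile"),
            cyst_fraction >= 0, cyst_fraction <= 1, n_cells >= 1L)
  reg <- allometry_registry()
  rdna_percell <- predict(reg$rdna_esd, esd)
  rrna_percell <- predict(power_law_fit(reg$rrna_total_esd$slope,
                                        reg$rrna_total_esd$intercept,
                                        "rRNA_CNPC", "ESD"), esd)
  n_cyst <- round(cyst_fraction * n_cells)
  n_veg <- n_cells - n_cyst
  s <- profile$cyst_rrna_suppression
  with_seed(seed, {
    noise <- function(k) 10^stats::rnorm(k, 0, noise_sd_log10)
    rdna_veg <- rdna_percell * noise(n_veg)
    rdna_cyst <- rdna_percell * noise(n_cyst)
    rrna_veg <- rrna_percell * noise(n_veg)
    rrna_cyst <- rrna_percell * s * noise(n_cyst)
    # rrna_rc is left at its default 0: a field population_pool() exposes
    # for when the cysts' own rRNA is actually known. The generated truth
    # is recorded as attributes for validation.
    pool <- population_pool(
      esd = esd,
      rdna_total = sum(rdna_veg) + sum(rdna_cyst),
      rrna_total = sum(rrna_veg) + sum(rrna_cyst),
      n_cells = n_cells)
    attr(pool, "true_fraction") <- n_cyst / n_cells
    attr(pool, "suppression") <- s
    attr(pool, "rrna_rc") <- sum(rrna_cyst)
    attr(pool, "rdna_rc") <- sum(rdna_cyst)
    pool
  })
}

#' Generate a qPCR dilution series
#'
#' CT values follow the standard-curve model
#' CT = intercept - log10(copies) / log10(1 + efficiency) + noise,
#' one point per decade, optionally with replicate reactions per point
#' (assays are conventionally run in triplicate).
#'
#' @param true_efficiency Amplification efficiency in [0.8, 1.2].
#' @param copies_decades Number of decades (points); the series spans
#'   log10 copies `start_log10 ... start_log10 + copies_decades - 1`.
#' @param ct_noise_sd Gaussian CT noise SD (cycles).
#' @param seed Integer seed.
#' @param start_log10 log10 copies of the most dilute standard (default 3).
#' @param intercept CT at a single copy (default 38).
#' @param n_replicates Reactions per dilution point (default 3).
#' @return data.frame: log10_copies, ct, replicate.
#' @export
gen_dilution_series <- function(true_efficiency = 1.0, copies_decades = 5L,
                                ct_noise_sd = 0, seed = NULL,
                                start_log10 = 3, intercept = 38,
                                n_replicates = 3L) {
  if (true_efficiency < 0.8 || true_efficiency > 1.2) {
    stop("gen_dilution_series(): efficiency must be in [0.8, 1.2]")
  }
  if (copies_decades < 1L) {
    stop("gen_dilution_series(): need at least one decade")
  }
  lg <- rep(start_log10 + seq_len(copies_decades) - 1, each = n_replicates)
  slope <- -1 / log10(1 + true_efficiency)
  with_seed(seed, {
    ct <- intercept + slope * lg + stats::rnorm(length(lg), 0, ct_noise_sd)
    data.frame(log10_copies = lg, ct = ct,
               replicate = rep(seq_len(n_replicates),
                               times = copies_decades))
  })
}

# Random ACGT template of the given length.
random_template <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
        collapse = "")
}

# Substitute k evenly spaced positions (cyclic base replacement, offset
# shifts the pattern so sibling variants mutate different sites). Spacing
# keeps substitutions isolated, so the optimal global alignment stays
# ungapped and the realised divergence is exactly k/length.
mutate_spaced <- function(sequence, k, offset = 0L) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  pos <- round(seq(1L + offset, L, length.out = k))
  bases <- c("A", "C", "G", "T")
  chars[pos] <- bases[(match(chars[pos], bases) %% 4L) + 1L]
  paste(chars, collapse = "")
}

# Substitute k random positions of a sequence (never to the same base);
# used for spurious error reads.
mutate_sequence <- function(sequence, k) {
  chars <- strsplit(sequence, "")[[1]]
  pos <- sample.int(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate a denoised single-cell variant pool
#'
#' A dominant variant (the template) receives `dominant_fraction` of the
#' reads; one minor variant per entry of `variant_divergences` is created
#' by substituting `round(d * L)` template positions, and the remaining
#' reads are split equally among minors. With a positive
#' `substitution_error_rate`, that fraction of reads is replaced by
#' spurious singletons each carrying one random substitution relative to
#' its (abundance-sampled) source variant; the rate is recorded in the
#' pool's `residual_error_rate`.
#'
#' @param profile A [species_profile()] (template length, divergences,
#'   dominant fraction); individual fields may be overridden.
#' @param read_depth Total reads (default 1600).
#' @param substitution_error_rate Residual per-read error rate in
#'   [0, 0.05].
#' @param seed Integer seed.
#' @param pool_type `"rDNA"` or `"rRNA"`.
#' @return A [variant_pool()] with attribute `"template"`.
#' @export
gen_variant_pool <- function(profile, read_depth = 1600L,
                             substitution_error_rate = 0, seed = NULL,
                             pool_type = "rDNA") {
  stopifnot(inherits(profile, "species_profile"),
            profile$template_length >= 100L)
  with_seed(seed, {
    template <- random_template(profile$template_length)
    divs <- profile$variant_divergences
    n_minor <- length(divs)
    dom_reads <- if (n_minor) {
      max(1L, round(profile$dominant_fraction * read_depth))
    } else {
      read_depth
    }
    seqs <- template
    counts <- dom_reads
    if (n_minor) {
      minor_total <- read_depth - dom_reads
      base <- minor_total %/% n_minor
      extra <- minor_total %% n_minor
      minor_counts <- rep(base, n_minor) + c(rep(1L, extra),
                                             rep(0L, n_minor - extra))
      minors <- vapply(seq_along(divs), function(i) {
        mutate_spaced(template,
                      max(1L, round(divs[i] * profile$template_length)),
                      offset = 3L * (i - 1L))
      }, character(1))
      keep <- minor_counts > 0L
      seqs <- c(seqs, minors[keep])
      counts <- c(counts, minor_counts[keep])
    }
    if (substitution_error_rate > 0) {
      n_err <- stats::rbinom(1L, read_depth, substitution_error_rate)
      n_err <- min(n_err, sum(counts) - length(counts))  # keep sources >= 1
      if (n_err > 0L) {
        for (i in seq_len(n_err)) {
          src <- sample.int(length(counts), 1L, prob = counts)
          counts[src] <- counts[src] - 1L
          seqs <- c(seqs, mutate_sequence(seqs[src], 1L))
          counts <- c(counts, 1L)
        }
      }
    }
    pool <- variant_pool(seqs, counts, cell_id = profile$name,
                         pool_type = pool_type,
                         residual_error_rate = substitution_error_rate)
    attr(pool, "template") <- template
    pool
  })
}

#' Generate a growth-rate data set from known model coefficients
#'
#' log10(r) = coef_t * t + coef_x * log10(x) + intercept + noise, over a
#' supplied or default design. The default 12-point design mirrors the
#' structure of the real data (4 species-like predictor levels crossed
#' with temperatures in 16-28 degrees C, predictor spanning >= 2 orders
#' of magnitude).
#'
#' @param coef_t,coef_x,intercept Generating coefficients.
#' @param design Optional data.frame with columns `t` and `x`; must be
#'   non-collinear with n >= 4.
#' @param noise_sd Gaussian SD on log10(r) (default 0).
#' @param seed Integer seed.
#' @return data.frame: r, t, x.
#' @export
gen_growth_dataset <- function(coef_t = 0.022, coef_x = -0.474,
                               intercept = 1.821, design = NULL,
                               noise_sd = 0, seed = NULL) {
  if (is.null(design)) {
    design <- expand.grid(t = c(16, 20, 24, 28), lx = c(3, 4, 5))
    design$x <- 10^design$lx
    design$lx <- NULL
  }
  stopifnot(all(c("t", "x") %in% names(design)), nrow(design) >= 4L,
            all(design$x > 0))
  if (qr(cbind(1, design$t, log10(design$x)))$rank < 3L) {
    stop("gen_growth_dataset(): collinear design")
  }
  with_seed(seed, {
    lr <- coef_t * design$t + coef_x * log10(design$x) + intercept +
      stats::rnorm(nrow(design), 0, noise_sd)
    data.frame(r = 10^lr, t = design$t, x = design$x)
  })
}
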