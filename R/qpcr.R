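# Absolute quantification from qPCR standard curves.

#' Amplification efficiency from a standard-curve slope
#'
#' E = 10^(-1/slope) - 1, where slope is the CT change per log10 copies.
#' Perfect per-cycle doubling gives slope -1/log10(2) ~ -3.3219 and E = 1
#' (100%).
#'
#' @param slope Standard-curve slope (CT per log10 copies); must be < 0.
#' @return Efficiency as a fraction (1.0 = 100%).
#' @export
efficiency_from_slope <- function(slope) {
  if (any(!is.finite(slope)) || any(slope >= 0)) {
    stop("efficiency_from_slope(): slope must be negative and finite")
  }
  10^(-1 / slope) - 1
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of CT on log10(copies) over a dilution series.
#' Replicate CTs at the same dilution may be averaged first
#' (`average_replicates = TRUE`) or all points used as-is. Amplification
#' efficiency is derived from the slope via [efficiency_from_slope()].
#' A non-negative slope yields no efficiency and the curve is flagged
#' invalid; efficiencies outside the conventional 0.9 <= 1 + E <= 1.2
#' window are flagged but returned.
#'
#' @param log10_copies log10 template copy numbers of the dilution points.
#' @param ct Threshold cycles, same length.
#' @param replicate Optional replicate labels (used only when averaging).
#' @param average_replicates Average CTs sharing a log10_copies value
#'   before fitting (default FALSE).
#' @return An object of class `standard_curve` with fields `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `n`, `valid`, `flag`.
#' @export
fit_standard_curve <- function(log10_copies, ct, replicate = NULL,
                               average_replicates = FALSE) {
  stopifnot(length(log10_copies) == length(ct))
  if (any(!is.finite(log10_copies)) || any(!is.finite(ct))) {
    stop("fit_standard_curve(): inputs must be finite")
  }
  if (isTRUE(average_replicates)) {
    ct <- as.numeric(tapply(ct, log10_copies, mean))
    log10_copies <- sort(unique(log10_copies))
  }
  if (length(unique(log10_copies)) < 3L) {
    stop("fit_standard_curve(): need >= 3 distinct dilution points")
  }
  fit <- stats::lm(ct ~ log10_copies)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- suppressWarnings(summary(fit))$r.squared
  valid <- slope < 0
  efficiency <- if (valid) efficiency_from_slope(slope) else NA_real_
  flag <- NULL
  if (!valid) {
    warning("fit_standard_curve(): non-negative slope; curve flagged invalid")
    flag <- "invalid_slope"
  } else if (1 + efficiency < 0.9 || 1 + efficiency > 1.2) {
    flag <- "efficiency_out_of_range"
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 efficiency = efficiency, n = length(ct), valid = valid,
                 flag = flag),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> CT = %.4f * log10(copies) + %.3f  (R2 = %.4f, E = %s, n = %d)%s\n",
    x$slope, x$intercept, x$r_squared,
    if (is.na(x$efficiency)) "NA" else sprintf("%.1f%%", 100 * x$efficiency),
    x$n, if (is.null(x$flag)) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}

#' Predict CT from template copies
#'
#' @param copies Template copy number (> 0).
#' @param curve A [fit_standard_curve()] result.
#' @return Predicted CT.
#' @export
ct_from_copies <- function(copies, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(copies <= 0)) stop("ct_from_copies(): copies must be > 0")
  curve$intercept + curve$slope * log10(copies)
}

#' Absolute copy number from a threshold cycle
#'
#' Inverts the standard curve: copies = 10^((ct - intercept)/slope).
#'
#' @param ct Threshold cycle(s).
#' @param curve A valid [fit_standard_curve()] result.
#' @return Estimated copies.
#' @export
copies_from_ct <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!curve$valid) stop("copies_from_ct(): curve is flagged invalid")
  10^((ct - curve$intercept) / curve$slope)
}

#' rRNA copies by subtraction of rDNA from the cDNA+DNA total
#'
#' Reverse-transcribed single-cell samples contain genomic rDNA alongside
#' cDNA, so rRNA copy numbers are obtained by subtracting the rDNA copy
#' number from the total quantified in the cDNA sample. Negative
#' differences (possible under measurement noise) clamp to zero with a
#' warning and a `"flag"` attribute.
#'
#' @param total_cdna_sample Copies quantified in the cDNA(+DNA) sample.
#' @param rdna Copies quantified in the genomic DNA sample.
#' @return rRNA copies, >= 0. Vectorised.
#' @export
rrna_by_subtraction <- function(total_cdna_sample, rdna) {
  if (any(total_cdna_sample < 0) || any(rdna < 0)) {
    stop("rrna_by_subtraction(): inputs must be non-negative")
  }
  out <- total_cdna_sample - rdna
  clamped <- out < 0
  if (any(clamped)) {
    warning("rrna_by_subtraction(): ", sum(clamped),
            " negative difference(s) clamped to zero")
    out[clamped] <- 0
    attr(out, "flag") <- clamped
  }
  out
}
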