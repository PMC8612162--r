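# Cell geometry and growth-rate computations.

#' Life-cycle stages recognised throughout the package
#'
#' Vegetative stages (lag, log, plateau) plus the two cystic forms: unstable
#' cysts (temporary, chill-induced, near-vegetative ribotype content) and
#' resting cysts (dormant, rRNA-depleted).
#'
#' @export
LIFE_STAGES <- c("lag", "log", "plateau", "unstable_cyst", "resting_cyst")

#' Volume of a prolate spheroid
#'
#' Fixed ciliate cells (and their macronuclei) are ellipsoid; volume is
#' computed by the standard spheroid formula (pi/6) * L * W^2, with the
#' length L as the major axis and the width W as both minor axes.
#'
#' @param length Major axis, um. Must be positive.
#' @param width Minor axis, um. Must be positive.
#' @return Volume in um^3. Vectorised over both arguments.
#' @examples
#' spheroid_volume(20, 10)   # 1047.2 um^3
#' spheroid_volume(10, 10)   # sphere: (pi/6) * 10^3
#' @export
spheroid_volume <- function(length, width) {
  if (any(!is.finite(length)) || any(!is.finite(width)) ||
      any(length <= 0) || any(width <= 0)) {
    stop("spheroid_volume(): length and width must be positive and finite")
  }
  (pi / 6) * length * width^2
}

#' Equivalent spherical diameter from cell volume
#'
#' Diameter of the sphere with the same volume as the cell: ESD =
#' (6 CV / pi)^(1/3). Inverse of the sphere-volume formula, so
#' `esd_from_volume(spheroid_volume(d, d)) == d`.
#'
#' @param cv Cell volume, um^3. Must be positive.
#' @return ESD in um. Vectorised.
#' @export
esd_from_volume <- function(cv) {
  if (any(!is.finite(cv)) || any(cv <= 0)) {
    stop("esd_from_volume(): cv must be positive and finite")
  }
  (6 * cv / pi)^(1 / 3)
}

#' Nucleocytoplasmic ratio
#'
#' Fraction of cell volume occupied by the macronucleus, MV/CV. Observed
#' values for vegetative and cystic Colpoda cells fall roughly between 1%
#' and 8%; a ratio >= 1 is biologically implausible and is returned with a
#' `"flag"` attribute rather than an error.
#'
#' @param mv Macronuclear volume, um^3.
#' @param cv Cell volume, um^3.
#' @return MV/CV as a fraction; attribute `"flag"` is TRUE where mv >= cv.
#' @export
nc_ratio <- function(mv, cv) {
  if (any(!is.finite(mv)) || any(!is.finite(cv)) ||
      any(mv <= 0) || any(cv <= 0)) {
    stop("nc_ratio(): mv and cv must be positive and finite")
  }
  ratio <- mv / cv
  implausible <- mv >= cv
  if (any(implausible)) {
    warning("nc_ratio(): macronuclear volume >= cell volume in ",
            sum(implausible), " case(s); result flagged")
    attr(ratio, "flag") <- implausible
  }
  ratio
}

#' Construct a growth curve
#'
#' @param times Sampling times, days; strictly increasing.
#' @param abundances Cell abundances, cells/ml; non-negative.
#' @param temperature Culturing temperature, degrees C.
#' @param species Species identifier.
#' @return An object of class `growth_curve`.
#' @export
growth_curve <- function(times, abundances, temperature = NA_real_,
                         species = NA_character_) {
  stopifnot(length(times) == length(abundances))
  if (length(times) < 2L) stop("growth_curve(): need at least 2 points")
  if (any(diff(times) <= 0)) stop("growth_curve(): times must be strictly increasing")
  if (any(abundances < 0)) stop("growth_curve(): abundances must be >= 0")
  structure(list(times = as.numeric(times),
                 abundances = as.numeric(abundances),
                 temperature = temperature, species = species),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> %s at %s degC, %d points over %.1f d\n",
              x$species, format(x$temperature), length(x$times),
              diff(range(x$times))))
  invisible(x)
}

#' Maximum specific growth rate from a growth curve
#'
#' The steepest log-phase slope of ln(abundance) versus time: ordinary
#' least-squares slopes are computed within every sliding window of
#' `window` consecutive positive-abundance points and the maximum is
#' returned, in d^-1. Zero-abundance points cannot enter the log transform
#' and are dropped with a warning.
#'
#' @param curve A [growth_curve()].
#' @param window Number of consecutive sampling points per regression
#'   window (default 3; shrunk to the number of available points if fewer).
#' @return Maximum growth rate, d^-1.
#' @export
max_growth_rate <- function(curve, window = 3L) {
  stopifnot(inherits(curve, "growth_curve"))
  keep <- curve$abundances > 0
  if (sum(keep) < 2L) {
    stop("max_growth_rate(): need at least 2 points with positive abundance")
  }
  if (!all(keep)) {
    warning("max_growth_rate(): dropping ", sum(!keep),
            " zero-abundance point(s)")
  }
  t <- curve$times[keep]
  ln_n <- log(curve$abundances[keep])
  n <- length(t)
  w <- max(2L, min(as.integer(window), n))
  slopes <- vapply(seq_len(n - w + 1L), function(i) {
    idx <- i:(i + w - 1L)
    tt <- t[idx]
    yy <- ln_n[idx]
    sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
  }, numeric(1))
  max(slopes)
}
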