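# Log-log power-law fitting and exact algebraic transformations among
# the parameterizations of the ribotype-phenotype scaling relations.

# log10(pi/6), the exact constant linking CV and ESD parameterizations:
# CV = (pi/6) * ESD^3.
LOG10_PI_6 <- log10(pi / 6)

#' Construct a power-law fit object
#'
#' A fitted (or tabulated) log10-log10 linear relation
#' log10(response) = intercept + slope * log10(predictor)
#' [+ log10(N) when `population = TRUE`].
#'
#' @param slope Dimensionless scaling exponent.
#' @param intercept Intercept on the log10 response scale.
#' @param response,predictor Axis labels (e.g. "rDNA_CNPC", "CV").
#' @param r_squared,p_value,n Fit statistics (NA for derived relations).
#' @param population TRUE when the relation includes an additive
#'   log10(N) population-abundance term.
#' @param log_response FALSE for relations whose response is fitted on the
#'   natural (untransformed) scale, e.g. OTU richness vs log10 copy number.
#' @return An object of class `power_law_fit`.
#' @export
power_law_fit <- function(slope, intercept, response = "y", predictor = "x",
                          r_squared = NA_real_, p_value = NA_real_,
                          n = NA_integer_, population = FALSE,
                          log_response = TRUE) {
  stopifnot(is.numeric(slope), is.numeric(intercept))
  structure(list(slope = as.numeric(slope),
                 intercept = as.numeric(intercept),
                 response = response, predictor = predictor,
                 r_squared = as.numeric(r_squared),
                 p_value = as.numeric(p_value),
                 n = as.integer(n),
                 population = isTRUE(population),
                 log_response = isTRUE(log_response)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  lhs <- if (x$log_response) paste0("log10(", x$response, ")") else x$response
  rhs <- sprintf("%s%.4g log10(%s) %+.4g",
                 if (x$population) "log10(N) + " else "",
                 x$slope, x$predictor, x$intercept)
  stats_txt <- sprintf("R2 = %s, p = %s, n = %s",
                       format(x$r_squared, digits = 3),
                       format(x$p_value, digits = 3),
                       format(x$n))
  cat(sprintf("<power_law_fit> %s = %s  (%s)\n", lhs, rhs, stats_txt))
  invisible(x)
}

#' Fit a power law by OLS on log10-transformed data
#'
#' Regresses log10(y) on log10(x). Both variables must be strictly
#' positive; offending rows are reported by index. A constant response is
#' returned as slope 0 with R-squared 0 (the regression explains nothing).
#'
#' @param x,y Paired positive observations (n >= 3).
#' @param response,predictor Axis labels carried into the result.
#' @return A [power_law_fit()] with slope, intercept, R-squared, the slope
#'   t-test p-value and n.
#' @export
fit_power_law <- function(x, y, response = "y", predictor = "x") {
  stopifnot(length(x) == length(y))
  bad <- which(!is.finite(x) | !is.finite(y) | x <= 0 | y <= 0)
  if (length(bad)) {
    stop("fit_power_law(): non-positive or non-finite values at rows ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  if (length(x) < 3L) stop("fit_power_law(): need n >= 3")
  lx <- log10(x)
  ly <- log10(y)
  if (isTRUE(all.equal(stats::var(ly), 0))) {
    return(power_law_fit(0, mean(ly), response, predictor,
                         r_squared = 0, p_value = NA_real_, n = length(x)))
  }
  fit <- stats::lm(ly ~ lx)
  sm <- suppressWarnings(summary(fit))  # noise-free data triggers a
                                        # "perfect fit" warning
  power_law_fit(slope = unname(stats::coef(fit)[2]),
                intercept = unname(stats::coef(fit)[1]),
                response = response, predictor = predictor,
                r_squared = sm$r.squared,
                p_value = sm$coefficients[2, 4],
                n = length(x))
}

#' Re-express a CV-based fit on the ESD basis
#'
#' Substituting CV = (pi/6) * ESD^3 into
#' log10(y) = b + a log10(CV) gives
#' log10(y) = b + a log10(pi/6) + 3a log10(ESD): the ESD slope is exactly
#' three times the CV slope, and the intercept shifts by a * log10(pi/6).
#'
#' @param fit A [power_law_fit()] with predictor "CV".
#' @return The equivalent fit with predictor "ESD".
#' @export
cv_fit_to_esd_fit <- function(fit) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (!identical(fit$predictor, "CV")) {
    stop("cv_fit_to_esd_fit(): fit predictor must be 'CV', got '",
         fit$predictor, "'")
  }
  out <- fit
  out$slope <- 3 * fit$slope
  out$intercept <- fit$intercept + fit$slope * LOG10_PI_6
  out$predictor <- "ESD"
  out
}

#' Lift a per-cell relation to the population total
#'
#' For an idealized population of N identical cells, the total copy number
#' is N times the per-cell value, i.e. the same power law plus an additive
#' log10(N) term. Coefficients are unchanged; the response label switches
#' from per-cell (CNPC) to total.
#'
#' @param fit A per-cell [power_law_fit()] (`population = FALSE`).
#' @return The population-level fit (`population = TRUE`).
#' @export
percell_to_population <- function(fit) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (fit$population) {
    stop("percell_to_population(): fit is already population-level")
  }
  out <- fit
  out$population <- TRUE
  out$response <- if (grepl("_CNPC", fit$response, fixed = TRUE)) {
    sub("_CNPC", "_total", fit$response, fixed = TRUE)
  } else {
    paste0(fit$response, "_total")
  }
  out
}

#' Ratio of two power laws sharing a predictor
#'
#' log10(num/den) = (b_num - b_den) + (a_num - a_den) log10(x). When both
#' relations are population-level the log10(N) terms cancel, so the ratio
#' is N-free.
#'
#' @param numerator,denominator [power_law_fit()] objects with identical
#'   predictor labels and matching population status.
#' @return A [power_law_fit()] for the ratio.
#' @export
ratio_fit <- function(numerator, denominator) {
  stopifnot(inherits(numerator, "power_law_fit"),
            inherits(denominator, "power_law_fit"))
  if (!identical(numerator$predictor, denominator$predictor)) {
    stop("ratio_fit(): predictor labels differ ('", numerator$predictor,
         "' vs '", denominator$predictor, "')")
  }
  if (!identical(numerator$population, denominator$population)) {
    stop("ratio_fit(): mixed per-cell and population-level fits")
  }
  power_law_fit(slope = numerator$slope - denominator$slope,
                intercept = numerator$intercept - denominator$intercept,
                response = paste0(numerator$response, "/",
                                  denominator$response),
                predictor = numerator$predictor,
                population = FALSE)
}

#' Evaluate a power-law fit
#'
#' Returns 10^(intercept + slope * log10(x)), multiplied by `n` for
#' population-level relations (for which `n` is mandatory). For
#' non-log-response fits the linear predictor intercept + slope*log10(x)
#' is returned directly.
#'
#' @param object A [power_law_fit()].
#' @param x Predictor value(s), > 0.
#' @param n Population abundance; required iff `object$population`.
#' @param ... Unused.
#' @return Predicted response value(s).
#' @export
predict.power_law_fit <- function(object, x, n = NULL, ...) {
  if (any(x <= 0)) stop("predict.power_law_fit(): x must be > 0")
  if (object$population && is.null(n)) {
    stop("predict.power_law_fit(): population-level fit requires n")
  }
  if (!object$population && !is.null(n)) {
    stop("predict.power_law_fit(): n supplied for a per-cell fit")
  }
  lin <- object$intercept + object$slope * log10(x)
  if (!object$log_response) return(lin)
  out <- 10^lin
  if (object$population) out <- out * n
  out
}

#' Registry of the fitted and derived allometric scaling relations
#'
#' The ten Colpoda-based relations linking per-cell and population 18S
#' rDNA/rRNA copy numbers to cell volume (CV, um^3), equivalent spherical
#' diameter (ESD, um) and macronuclear volume (MV, um^3), plus the derived
#' population rRNA:rDNA ratio relation used by the resting-cyst estimator.
#' Coefficients are stored exactly as published, not re-derived, so
#' independently refit intercepts (e.g. 0.396 on the ESD basis vs the
#' 0.398 obtained by exact transformation of the CV fit) are preserved.
#'
#' Relations fitted across all life-cycle stages are suffixed
#' `_allstages`; `_veg` relations exclude resting cysts, whose rRNA
#' content falls orders of magnitude below the size expectation.
#'
#' @return Named list of [power_law_fit()] objects:
#'   `rdna_cv`, `rdna_esd`, `rdna_total_esd`, `rrna_cv_allstages`,
#'   `rrna_cv_veg`, `rrna_total_esd`, `rrna_rdna_ratio_esd`,
#'   `rdna_mv`, `rrna_mv_allstages`, `rrna_mv_veg`.
#' @export
allometry_registry <- function() {
  list(
    rdna_cv = power_law_fit(0.76, 0.61, "rDNA_CNPC", "CV",
                            r_squared = 0.91, p_value = 0.001, n = 20),
    rdna_esd = power_law_fit(2.28, 0.396, "rDNA_CNPC", "ESD",
                             r_squared = 0.91, p_value = 0.001, n = 20),
    rdna_total_esd = power_law_fit(2.28, 0.396, "rDNA_total", "ESD",
                                   r_squared = 0.91, p_value = 0.001,
                                   n = 20, population = TRUE),
    rrna_cv_allstages = power_law_fit(1.24, 1.69, "rRNA_CNPC", "CV",
                                      r_squared = 0.37, p_value = 0.005,
                                      n = 20),
    rrna_cv_veg = power_law_fit(0.87, 3.67, "rRNA_CNPC", "CV",
                                r_squared = 0.84, p_value = 0.001, n = 16),
    rrna_total_esd = power_law_fit(2.61, 3.43, "rRNA_total", "ESD",
                                   r_squared = 0.84, p_value = 0.001,
                                   n = 16, population = TRUE),
    rrna_rdna_ratio_esd = power_law_fit(0.33, 3.034,
                                        "rRNA_total/rDNA_total", "ESD"),
    rdna_mv = power_law_fit(0.90, 1.44, "rDNA_CNPC", "MV",
                            r_squared = 0.93, p_value = 0.001, n = 16),
    rrna_mv_allstages = power_law_fit(1.70, 2.28, "rRNA_CNPC", "MV",
                                      r_squared = 0.50, p_value = 0.002,
                                      n = 16),
    rrna_mv_veg = power_law_fit(1.05, 4.47, "rRNA_CNPC", "MV",
                                r_squared = 0.83, p_value = 0.001, n = 12)
  )
}
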