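# Bivariate growth-rate prediction models: log10(r) as a linear function
# of temperature and one log10-transformed ribotypic/phenotypic predictor.

#' Construct a growth-model fit object
#'
#' log10(r) = coef_t * t + coef_x * log10(x) + intercept, with r the
#' maximum growth rate (d^-1), t the temperature (degrees C), and x a
#' per-cell ribotypic or phenotypic predictor.
#'
#' @param coef_t Temperature coefficient, per degree C.
#' @param coef_x Coefficient on log10(predictor).
#' @param intercept Intercept, log10 d^-1.
#' @param predictor One of `"rDNA_CNPC"`, `"rRNA_CNPC/rDNA_CNPC"`,
#'   `"rRNA_CNPC"`, `"CV"`.
#' @param r_squared,p_value,n Fit statistics.
#' @param response Fitted response values (internal; used to verify that
#'   compared models share a data set).
#' @return An object of class `growth_model_fit`.
#' @export
growth_model_fit <- function(coef_t, coef_x, intercept,
                             predictor = "rDNA_CNPC",
                             r_squared = NA_real_, p_value = NA_real_,
                             n = NA_integer_, response = NULL) {
  structure(list(coef_t = as.numeric(coef_t), coef_x = as.numeric(coef_x),
                 intercept = as.numeric(intercept), predictor = predictor,
                 r_squared = as.numeric(r_squared),
                 p_value = as.numeric(p_value), n = as.integer(n),
                 response = response),
            class = "growth_model_fit")
}

#' @export
print.growth_model_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_model_fit> log10(r) = %.4g t %+.4g log10(%s) %+.4g  (R2 = %s, n = %s)\n",
    x$coef_t, x$coef_x, x$predictor,
    x$intercept, format(x$r_squared, digits = 3), format(x$n)))
  invisible(x)
}

#' Fit a growth-rate model
#'
#' OLS of log10(r) on temperature and log10(x). The design must be of
#' full rank: a constant predictor or temperature column (or an exact
#' linear dependence between them) raises a rank-deficiency error.
#'
#' @param r Maximum growth rates, d^-1 (> 0).
#' @param t Temperatures, degrees C.
#' @param x Predictor values (> 0).
#' @param predictor Predictor label.
#' @return A [growth_model_fit()] with coefficients, R-squared, the
#'   overall F-test p-value and n.
#' @export
fit_growth_model <- function(r, t, x, predictor = "rDNA_CNPC") {
  stopifnot(length(r) == length(t), length(r) == length(x))
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("fit_growth_model(): r must be positive and finite")
  }
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("fit_growth_model(): x must be positive and finite")
  }
  if (length(r) < 4L) stop("fit_growth_model(): need n >= 4")
  lx <- log10(x)
  design <- cbind(1, t, lx)
  if (qr(design)$rank < 3L) {
    stop("fit_growth_model(): rank-deficient design (collinear or constant predictors)")
  }
  lr <- log10(r)
  fit <- stats::lm(lr ~ t + lx)
  sm <- suppressWarnings(summary(fit))
  fstat <- sm$fstatistic
  p <- unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  growth_model_fit(coef_t = unname(stats::coef(fit)["t"]),
                   coef_x = unname(stats::coef(fit)["lx"]),
                   intercept = unname(stats::coef(fit)[1]),
                   predictor = predictor,
                   r_squared = sm$r.squared, p_value = p,
                   n = length(r), response = lr)
}

#' Predict a maximum growth rate
#'
#' @param fit A [growth_model_fit()].
#' @param t Temperature, degrees C.
#' @param x Predictor value (> 0).
#' @return Predicted growth rate, d^-1. Vectorised.
#' @export
predict_growth_rate <- function(fit, t, x) {
  stopifnot(inherits(fit, "growth_model_fit"))
  if (any(x <= 0)) stop("predict_growth_rate(): x must be > 0")
  10^(fit$coef_t * t + fit$coef_x * log10(x) + fit$intercept)
}

#' Rank competing growth models by explained variance
#'
#' Orders fits by descending R-squared and annotates the drop relative to
#' the best model. Fits carrying response data must share it (same
#' response values), otherwise the comparison is meaningless and errors;
#' tabulated fits without stored response are compared as given.
#'
#' @param fits List of >= 2 [growth_model_fit()] objects.
#' @return data.frame with columns `predictor`, `r_squared`,
#'   `delta_r_squared`, `n`, ordered by descending R-squared (ties keep
#'   input order).
#' @export
compare_models <- function(fits) {
  if (!is.list(fits) || length(fits) < 2L) {
    stop("compare_models(): need >= 2 fits")
  }
  stopifnot(all(vapply(fits, inherits, logical(1), "growth_model_fit")))
  responses <- Filter(Negate(is.null), lapply(fits, `[[`, "response"))
  if (length(responses) > 1L) {
    same <- vapply(responses[-1], function(rr) {
      isTRUE(all.equal(sort(rr), sort(responses[[1]])))
    }, logical(1))
    if (!all(same)) {
      stop("compare_models(): fits were made on different response data")
    }
  }
  r2 <- vapply(fits, `[[`, numeric(1), "r_squared")
  ord <- order(-r2)  # stable: ties keep input order
  out <- data.frame(
    predictor = vapply(fits, `[[`, character(1), "predictor")[ord],
    r_squared = r2[ord],
    delta_r_squared = max(r2) - r2[ord],
    n = vapply(fits, `[[`, integer(1), "n")[ord],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Registry of the published growth-rate models
#'
#' The four bivariate models predicting maximum growth rate from
#' temperature plus one predictor, fitted across four ciliate species
#' (two Colpoda, Euplotes vannus, Strombidium sulcatum). Per-cell rDNA
#' copy number is by far the best predictor (R2 = 0.89), followed by the
#' rRNA:rDNA copy-number ratio (0.76); per-cell rRNA (0.34) and cell
#' volume (0.33) predict poorly.
#'
#' @return Named list of [growth_model_fit()] objects:
#'   `rdna`, `ratio`, `rrna`, `cv`.
#' @export
growth_registry <- function() {
  list(
    rdna = growth_model_fit(0.022, -0.474, 1.821, "rDNA_CNPC",
                            r_squared = 0.89, p_value = 0.001, n = 12),
    ratio = growth_model_fit(0.036, 0.289, -1.355, "rRNA_CNPC/rDNA_CNPC",
                             r_squared = 0.76, p_value = 0.001, n = 12),
    rrna = growth_model_fit(0.057, 0.229, -2.746, "rRNA_CNPC",
                            r_squared = 0.34, p_value = 0.064, n = 12),
    cv = growth_model_fit(0.055, 0.206, -1.92, "CV",
                          r_squared = 0.33, p_value = 0.069, n = 12)
  )
}
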