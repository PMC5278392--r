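#' Median absolute deviation
#'
#' Robust dispersion: `scale * median(|x - median(x)|)`. The default scale
#' 1.4826 makes the estimate consistent for the standard deviation under
#' normality, the convention usual in robust Z-factor work; pass `scale = 1`
#' for the raw MAD.
#'
#' @param values numeric vector (nonempty).
#' @param scale consistency factor (default 1.4826).
#' @return scalar MAD.
#' @export
median_abs_deviation <- function(values, scale = 1.4826) {
  if (!length(values)) stop("no data: empty vector", call. = FALSE)
  scale * median(abs(values - median(values)))
}

#' Robust Z'-factor of assay quality
#'
#' Outlier-insensitive version of the Z'-factor, replacing means with
#' medians and standard deviations with (scaled) median absolute
#' deviations:
#' \deqn{Z' = 1 - \frac{3\,(\mathrm{MAD}_s + \mathrm{MAD}_c)}
#'                     {|\tilde{x}_s - \tilde{x}_c|}}
#' where \eqn{\tilde{x}} denotes the median of the sample and
#' negative-control groups. Values approach 1 for a perfectly separated
#' assay and fall below 0 when the signal bands overlap.
#'
#' @param sample numeric vector of per-spheroid sample measurements
#'   (length >= 2).
#' @param control numeric vector of negative-control measurements
#'   (length >= 2).
#' @param mad_scale MAD consistency factor, see [median_abs_deviation()].
#' @return scalar Z' (always <= 1).
#' @export
robust_z_prime <- function(sample, control, mad_scale = 1.4826) {
  if (length(sample) < 2 || length(control) < 2)
    stop("both groups need at least 2 measurements", call. = FALSE)
  ms <- median(sample); mc <- median(control)
  if (ms == mc)
    stop("undefined separation: sample and control medians are identical",
         call. = FALSE)
  1 - 3 * (median_abs_deviation(sample, mad_scale) +
           median_abs_deviation(control, mad_scale)) / abs(ms - mc)
}

#' Classify assay quality from a Z'-factor
#'
#' Applies the common acceptance rule: an assay is acceptable when
#' `Z' > 0.5` (strict inequality).
#'
#' @param z scalar Z'-factor (finite).
#' @return `"acceptable"` or `"unacceptable"`.
#' @export
classify_assay <- function(z) {
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z))
    stop("`z` must be a finite scalar", call. = FALSE)
  if (z > 0.5) "acceptable" else "unacceptable"
}

#' Default half-log dose grid
#'
#' Nine geometrically spaced doses spanning 0.01-300 uM (approximately
#' half-log steps), the grid of the reference etoposide design.
#'
#' @param from,to dose range in uM.
#' @param n number of doses.
#' @return numeric vector of doses.
#' @export
half_log_doses <- function(from = 0.01, to = 300, n = 9) {
  10^seq(log10(from), log10(to), length.out = n)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' \deqn{y = bottom + \frac{top - bottom}{1 + (x / IC_{50})^{hill}}}
#' parameterised on log10(dose) (the IC50 is fitted as log10(IC50)),
#' using Levenberg-Marquardt least squares. With `constrain_bottom_zero`
#' the bottom plateau is fixed at 0, as is conventional when the response
#' is known to vanish at saturating dose. The 95% confidence interval for
#' the IC50 is a Wald interval on the log10 scale. Zero doses (untreated
#' controls) are offset to `dose_floor`, by default one decade below the
#' smallest nonzero dose.
#'
#' @param doses numeric vector of doses (uM), nonnegative.
#' @param responses numeric vector of responses, same length.
#' @param constrain_bottom_zero fix `bottom = 0`.
#' @param dose_floor dose substituted for zero-dose points.
#' @return an object of class `dr_fit`: `top`, `bottom`, `ic50`, `hill`,
#'   `ic50_ci` (95%), `constrained_bottom`, `rss`, `converged`, and the
#'   underlying `nls` fit.
#' @export
fit_4pl <- function(doses, responses, constrain_bottom_zero = FALSE,
                    dose_floor = NULL) {
  if (length(doses) != length(responses))
    stop("`doses` and `responses` must have equal length", call. = FALSE)
  if (any(!is.finite(responses)))
    stop("responses must be finite", call. = FALSE)
  if (any(doses < 0)) stop("doses must be nonnegative", call. = FALSE)
  nz <- doses[doses > 0]
  if (!length(nz)) stop("all doses are zero", call. = FALSE)
  if (is.null(dose_floor)) dose_floor <- min(nz) / 10
  x <- ifelse(doses > 0, doses, dose_floor)
  need <- if (constrain_bottom_zero) 4L else 5L
  if (length(unique(x)) < need)
    stop(sprintf("need >= %d distinct doses for this fit", need),
         call. = FALSE)
  if (diff(range(responses)) < 1e-12)
    stop("fit failure: responses are constant (degenerate)", call. = FALSE)
  lx <- log10(x)
  df <- data.frame(lx = lx, y = responses)
  # starting values: plateaus from the data, hill sign from the trend
  slope <- stats::coef(stats::lm(y ~ lx, df))[2]
  # top is the larger plateau in either orientation; only the Hill sign
  # encodes whether the response falls (hill > 0) or rises with dose
  hill0 <- if (slope <= 0) 1 else -1
  lic0 <- median(lx)
  top0 <- max(responses)
  bot0 <- min(responses)
  fit <- tryCatch({
    if (constrain_bottom_zero) {
      minpack.lm::nlsLM(
        y ~ top / (1 + 10^(hill * (lx - lic))),
        data = df, start = list(top = max(top0, 1e-6), lic = lic0,
                                hill = hill0),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(hill * (lx - lic))),
        data = df, start = list(top = top0, bottom = bot0, lic = lic0,
                                hill = hill0),
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e)
    stop("fit failure: ", conditionMessage(e), call. = FALSE))
  cf <- coef(fit)
  se_lic <- tryCatch(sqrt(diag(vcov(fit)))[["lic"]], error = function(e) NA)
  ic50 <- 10^cf[["lic"]]
  ci <- if (is.finite(se_lic))
    10^(cf[["lic"]] + c(-1, 1) * 1.959964 * se_lic)
  else c(NA_real_, NA_real_)
  structure(list(
    top = cf[["top"]],
    bottom = if (constrain_bottom_zero) 0 else cf[["bottom"]],
    ic50 = ic50, hill = cf[["hill"]], ic50_ci = ci,
    constrained_bottom = constrain_bottom_zero,
    rss = sum(stats::residuals(fit)^2),
    converged = fit$convInfo$isConv %||% TRUE,
    fit = fit
  ), class = "dr_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dr_fit <- function(x, ...) {
  cat(sprintf(
    "4PL fit: top %.3g, bottom %.3g%s, IC50 %.3g uM (95%% CI %.3g-%.3g), hill %.3g\n",
    x$top, x$bottom, if (x$constrained_bottom) " (constrained)" else "",
    x$ic50, x$ic50_ci[1], x$ic50_ci[2], x$hill))
  invisible(x)
}

#' Evaluate a 4PL curve
#'
#' @param doses numeric doses.
#' @param top,bottom,ic50,hill curve parameters.
#' @return predicted responses.
#' @export
predict_4pl <- function(doses, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (doses / ic50)^hill)
}
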