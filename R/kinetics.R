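#' Eyring analysis of temperature-dependent exit rates
#'
#' Ordinary least squares of \eqn{\ln(k_{off}/T)} on \eqn{1/T}, with
#' \eqn{k_{off} = 1/\tau_{off}}. The transition-state parameters follow
#' from the line: \eqn{\Delta H = -\mathrm{slope}\cdot R} and
#' \eqn{\Delta S = (\mathrm{intercept} - \ln(k_B/h))\cdot R}. A noiseless
#' series generated from the Eyring relation is recovered to machine
#' precision.
#'
#' @param temperature_K absolute temperatures, K (>= 3 distinct values).
#' @param tau_off_s dwell-time constants at those temperatures, s (> 0).
#' @return object of class `eyring_fit` with `delta_H` (kJ/mol), `delta_S`
#'   (J/(mol K)), `slope`, `intercept`, `r_squared` and the points used.
#' @examples
#' k <- eyring_koff(c(283.15, 288.15, 297.15), 47740, -20.3)
#' eyring_fit(c(283.15, 288.15, 297.15), 1 / k)
#' @export
eyring_fit <- function(temperature_K, tau_off_s) {
  if (length(temperature_K) < 3 || length(unique(temperature_K)) < 3)
    stop("need >= 3 distinct temperatures", call. = FALSE)
  stopifnot(length(temperature_K) == length(tau_off_s))
  if (any(tau_off_s <= 0)) stop("tau_off must be > 0", call. = FALSE)
  if (any(temperature_K <= 0)) stop("temperatures must be in kelvin", call. = FALSE)
  k_off <- 1 / tau_off_s
  xi <- 1 / temperature_K
  yi <- log(k_off / temperature_K)
  fit <- stats::lm(yi ~ xi)
  cf <- stats::coef(fit)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((yi - mean(yi))^2)
  structure(list(
    delta_H = -unname(cf["xi"]) * .R_GAS / 1000,
    delta_S = (unname(cf["(Intercept)"]) - log(.K_BOLTZ / .H_PLANCK)) * .R_GAS,
    slope = unname(cf["xi"]), intercept = unname(cf["(Intercept)"]),
    r_squared = r2,
    points = data.frame(temperature_K = temperature_K,
                        tau_off_s = tau_off_s)
  ), class = "eyring_fit")
}

#' @export
print.eyring_fit <- function(x, ...) {
  cat("<eyring_fit>\n")
  cat(sprintf("  delta_H = %.4f kJ/mol\n  delta_S = %.4f J/(mol K)\n",
              x$delta_H, x$delta_S))
  cat(sprintf("  ln(koff/T) = %.4f + %.2f * (1/T),  R^2 = %.6f  (n = %d)\n",
              x$intercept, x$slope, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' @export
coef.eyring_fit <- function(object, ...) {
  c(delta_H_kJ_mol = object$delta_H, delta_S_J_molK = object$delta_S)
}

#' @export
predict.eyring_fit <- function(object, temperature_K = object$points$temperature_K,
                               ...) {
  k <- eyring_koff(temperature_K, object$delta_H * 1000, object$delta_S)
  data.frame(temperature_K = temperature_K, k_off = k, tau_off_s = 1 / k)
}

#' @export
plot.eyring_fit <- function(x, ...) {
  xi <- 1 / x$points$temperature_K
  yi <- log((1 / x$points$tau_off_s) / x$points$temperature_K)
  graphics::plot(xi, yi, xlab = "1/T (1/K)", ylab = "ln(k_off / T)",
                 main = "Eyring plot", ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  invisible(x)
}

#' Population dwell-time constant from event durations
#'
#' \eqn{\tau_{off}} at one temperature, in seconds. The default is the
#' statistical duration (10 to the power of the fitted log10-duration peak,
#' from [fit_duration_peak()]); `method = "mean"` uses the arithmetic mean
#' duration instead.
#'
#' @param features a `feature_table` (or numeric durations, ms); >= 50
#'   events.
#' @param method `"statistical"` (default) or `"mean"`.
#' @return tau_off in seconds.
#' @export
tau_from_durations <- function(features, method = c("statistical", "mean")) {
  method <- match.arg(method)
  d <- if (is.numeric(features)) features else features$duration_ms
  if (method == "statistical") {
    fit <- fit_duration_peak(d)
    attr(fit, "statistical_duration_ms") * 1e-3
  } else {
    mean(d) * 1e-3
  }
}
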