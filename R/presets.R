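#' @keywords internal
"_PACKAGE"

# Physical constants (SI)
.R_GAS <- 8.314        # J/(mol K)
.K_BOLTZ <- 1.380649e-23  # J/K
.H_PLANCK <- 6.62607015e-34  # J s

# Reference recording condition for all presets: +160 mV, 10 degC
.REF_TEMP_C <- 10
.REF_VOLTAGE_MV <- 160

#' Peptide classes handled by the package
#' @export
GLYCO_CLASSES <- c("WT", "Tn", "TF", "STn", "STF")

#' Transition-state thermodynamics of peptide-pore interaction
#'
#' Activation enthalpy and entropy of the event-exit process for the
#' unmodified (WT) and GalNAc-modified (Tn) MUC1 peptides, as obtained from
#' Eyring analysis of temperature-dependent dwell times. These describe the
#' strength of the peptide-nanopore interaction (the GalNAc modification
#' raises the enthalpic barrier) and are the reference inputs for
#' [eyring_fit()] round-trip analyses.
#'
#' @format A data frame with columns `class`, `delta_H_kJ_mol` and
#'   `delta_S_J_molK`.
#' @seealso [eyring_fit()], [eyring_koff()]
#' @export
thermo_constants <- data.frame(
  class = c("WT", "Tn"),
  delta_H_kJ_mol = c(25.89, 47.74),
  delta_S_J_molK = c(-95.2, -20.3),
  stringsAsFactors = FALSE
)

#' Solve for the activation enthalpy giving a target dwell-time ratio
#'
#' Inverts the Eyring dwell ratio
#' \eqn{\tau(T_1)/\tau(T_2) = (T_2/T_1)\exp[\Delta H/R (1/T_1 - 1/T_2)]}
#' for \eqn{\Delta H}. Used to calibrate simulator presets so that the
#' cold/warm statistical-duration ratio matches an observed factor.
#'
#' @param ratio target \eqn{\tau(T_1)/\tau(T_2)} (dimensionless, > 0).
#' @param t1_C,t2_C the two bath temperatures in degrees Celsius
#'   (defaults 10 and 24).
#' @return activation enthalpy in J/mol.
#' @examples
#' delta_h_for_ratio(1.5) / 1000  # kJ/mol giving a 1.5x slow-down on cooling
#' @export
delta_h_for_ratio <- function(ratio, t1_C = 10, t2_C = 24) {
  stopifnot(is.numeric(ratio), ratio > 0)
  T1 <- t1_C + 273.15
  T2 <- t2_C + 273.15
  .R_GAS * log(ratio * T1 / T2) / (1 / T1 - 1 / T2)
}

#' Construct a simulator preset for one peptide class
#'
#' A preset bundles the emission model of one analyte class: the blockade
#' ratio (I/I0) mixture, the log-normal dwell model at the reference
#' condition (+160 mV, 10 degC), the activation enthalpy governing how the
#' dwell scales with temperature, and the capture rate per micromolar.
#'
#' The entropy `delta_S` may be omitted, in which case it is derived so the
#' absolute Eyring rate at the reference temperature reproduces the preset's
#' reference dwell `10^dwell_log10_mean` ms (self-consistent preset).
#'
#' @param name class label.
#' @param ratio_components data frame or matrix with columns
#'   `weight`, `mean`, `sd`: the Gaussian mixture of I/I0. Weights must sum
#'   to 1 and means lie strictly in (0, 1).
#' @param dwell_log10_mean mean of log10(duration/ms) at the reference
#'   condition.
#' @param dwell_log10_sd standard deviation of log10(duration/ms), > 0.
#' @param delta_H activation enthalpy, J/mol (sets the temperature
#'   dependence of the dwell).
#' @param delta_S activation entropy, J/(mol K), or `NULL` to derive it.
#' @param capture_rate_per_uM events per second per micromolar at the
#'   reference condition.
#' @return an object of class `class_preset`.
#' @examples
#' p <- class_preset("WT",
#'   data.frame(weight = 1, mean = 0.45, sd = 0.02),
#'   dwell_log10_mean = 0.60, dwell_log10_sd = 0.35,
#'   delta_H = delta_h_for_ratio(1.5), capture_rate_per_uM = 0.3)
#' p
#' @export
class_preset <- function(name, ratio_components, dwell_log10_mean,
                         dwell_log10_sd, delta_H, delta_S = NULL,
                         capture_rate_per_uM) {
  rc <- as.data.frame(ratio_components)
  stopifnot(all(c("weight", "mean", "sd") %in% names(rc)))
  if (abs(sum(rc$weight) - 1) > 1e-8)
    stop("ratio component weights must sum to 1", call. = FALSE)
  if (any(rc$mean <= 0 | rc$mean >= 1))
    stop("all component means (I/I0) must lie strictly in (0, 1)", call. = FALSE)
  if (any(rc$sd <= 0)) stop("component sds must be > 0", call. = FALSE)
  if (dwell_log10_sd <= 0) stop("dwell_log10_sd must be > 0", call. = FALSE)
  if (capture_rate_per_uM <= 0) stop("capture_rate_per_uM must be > 0", call. = FALSE)
  # detectability: most events must survive the 0.50 ms duration filter
  p_detect <- stats::pnorm(log10(0.50), dwell_log10_mean, dwell_log10_sd,
                           lower.tail = FALSE)
  if (p_detect <= 0.5)
    stop("dwell model gives P(duration >= 0.50 ms) <= 0.5 at reference condition",
         call. = FALSE)
  Tref <- .REF_TEMP_C + 273.15
  if (is.null(delta_S)) {
    tau_ref_s <- 10^dwell_log10_mean * 1e-3
    k_ref <- 1 / tau_ref_s
    delta_S <- .R_GAS * (log(k_ref / Tref) - log(.K_BOLTZ / .H_PLANCK)) +
      delta_H / Tref
  }
  structure(list(
    name = name,
    ratio_components = rc[order(-rc$weight), , drop = FALSE],
    dwell_log10_mean = dwell_log10_mean,
    dwell_log10_sd = dwell_log10_sd,
    delta_H = delta_H,
    delta_S = delta_S,
    capture_rate_per_uM = capture_rate_per_uM
  ), class = "class_preset")
}

#' @export
print.class_preset <- function(x, ...) {
  cat(sprintf("<class_preset '%s'>\n", x$name))
  cat("  I/I0 mixture:\n")
  for (i in seq_len(nrow(x$ratio_components)))
    cat(sprintf("    w = %.2f  mean = %.3f  sd = %.3f\n",
                x$ratio_components$weight[i], x$ratio_components$mean[i],
                x$ratio_components$sd[i]))
  cat(sprintf("  dwell: log10(ms) ~ N(%.3f, %.3f); reference dwell %.2f ms\n",
              x$dwell_log10_mean, x$dwell_log10_sd, 10^x$dwell_log10_mean))
  cat(sprintf("  delta_H = %.2f kJ/mol, delta_S = %.1f J/(mol K)\n",
              x$delta_H / 1000, x$delta_S))
  cat(sprintf("  capture rate = %.3g events/s/uM at +160 mV, 10 degC\n",
              x$capture_rate_per_uM))
  invisible(x)
}

#' Default presets for the five MUC1 glycopeptide classes
#'
#' Blockade-ratio peak centers follow the Gaussian-fit values at +160 mV and
#' 10 degC: 0.45 (WT), 0.36 (Tn), 0.33 (TF), 0.18 (STn), 0.10 (STF). The
#' sialylated classes (STn, STF) are two-component mixtures: a dominant
#' population at the fitted peak (weight 0.7) and a shallower secondary
#' population (weight 0.3) whose centers (0.26 and 0.24) largely overlap
#' each other -- these secondary events form the merging region (MR) class.
#' Component SDs (0.02 single-population, 0.025 sialylated), dwell-time
#' centers, and capture rates are synthetic calibration choices and are
#' documented in the package vignette; none of them is consumed implicitly
#' by the analysis stages.
#'
#' Dwell temperature dependence: WT and Tn activation enthalpies are
#' calibrated with [delta_h_for_ratio()] so that cooling from 24 to 10 degC
#' lengthens the statistical duration by 1.5x (WT) and 1.8x (Tn); TF and the
#' sialylated classes use factors 1.6 and 1.4 (uncharacterized; see
#' vignette).
#'
#' @param classes subset of [GLYCO_CLASSES] to return.
#' @return named list of [class_preset()] objects.
#' @examples
#' default_presets(c("WT", "Tn"))
#' @export
default_presets <- function(classes = GLYCO_CLASSES) {
  stopifnot(all(classes %in% GLYCO_CLASSES))
  one <- function(mean, sd = 0.02) data.frame(weight = 1, mean = mean, sd = sd)
  two <- function(m1, m2, sd = 0.025)
    data.frame(weight = c(0.7, 0.3), mean = c(m1, m2), sd = sd)
  all <- list(
    WT = class_preset("WT", one(0.45), 0.60, 0.35,
                      delta_h_for_ratio(1.5), capture_rate_per_uM = 0.30),
    Tn = class_preset("Tn", one(0.36), 0.50, 0.35,
                      delta_h_for_ratio(1.8), capture_rate_per_uM = 0.35),
    TF = class_preset("TF", one(0.33), 0.30, 0.35,
                      delta_h_for_ratio(1.6), capture_rate_per_uM = 0.80),
    STn = class_preset("STn", two(0.18, 0.26), 0.15, 0.32,
                       delta_h_for_ratio(1.4), capture_rate_per_uM = 0.50),
    STF = class_preset("STF", two(0.10, 0.24), 0.05, 0.32,
                       delta_h_for_ratio(1.4), capture_rate_per_uM = 0.70)
  )
  all[classes]
}

#' Eyring exit rate
#'
#' Transition-state exit rate
#' \eqn{k_{off}(T) = (k_B T / h)\, e^{\Delta S/R - \Delta H/(R T)}}.
#'
#' @param temperature_K absolute temperature, K.
#' @param delta_H activation enthalpy, J/mol.
#' @param delta_S activation entropy, J/(mol K).
#' @return exit rate in 1/s.
#' @export
eyring_koff <- function(temperature_K, delta_H, delta_S) {
  stopifnot(all(temperature_K > 0))
  (.K_BOLTZ * temperature_K / .H_PLANCK) *
    exp(delta_S / .R_GAS - delta_H / (.R_GAS * temperature_K))
}

#' Temperature scaling of the mean dwell time
#'
#' Dimensionless multiplier \eqn{\tau(T)/\tau(T_{ref})} implied by the
#' Eyring model; only the activation enthalpy enters the ratio. Cooling
#' below the reference temperature lengthens the dwell whenever
#' \eqn{\Delta H > R T}.
#'
#' @param preset a [class_preset()] (its `delta_H` is used).
#' @param temperature_C bath temperature, degrees Celsius (0-60).
#' @param ref_temperature_C reference temperature, degrees Celsius
#'   (default 10, the preset calibration condition).
#' @return dimensionless dwell multiplier.
#' @examples
#' wt <- default_presets("WT")$WT
#' dwell_scale(wt, 24)  # warmer than reference: < 1
#' @export
dwell_scale <- function(preset, temperature_C,
                        ref_temperature_C = .REF_TEMP_C) {
  stopifnot(inherits(preset, "class_preset"))
  if (any(temperature_C < 0 | temperature_C > 60))
    stop("temperature must be within 0-60 degC", call. = FALSE)
  T1 <- temperature_C + 273.15
  Tref <- ref_temperature_C + 273.15
  (Tref / T1) * exp(preset$delta_H / .R_GAS * (1 / T1 - 1 / Tref))
}
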