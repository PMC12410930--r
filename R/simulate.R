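#' Simulation configuration
#'
#' Bundles everything needed to synthesize an ionic-current recording:
#' class presets, per-class analyte concentrations, trace geometry, baseline
#' model (open-pore level, white noise SD, slow sinusoidal drift), a rate of
#' spurious gating/outlier blockades, and the RNG seed. A fixed config and
#' seed fully determine the output.
#'
#' @param presets named list of [class_preset()] objects.
#' @param concentrations named numeric vector, micromolar per class; names
#'   must match preset names. Classes may be omitted (treated as 0).
#' @param duration_s trace length in seconds (> 0).
#' @param baseline_i0 open-pore current, pA.
#' @param baseline_sigma baseline white-noise SD, pA (> 0).
#' @param drift_amplitude amplitude of the slow sinusoidal baseline drift,
#'   pA (0 disables drift).
#' @param outlier_rate rate of spurious gating/outlier blockades, events/s.
#' @param temperature_C bath temperature, degrees Celsius.
#' @param voltage_mV applied potential, mV (metadata; presets are defined at
#'   +160 mV).
#' @param sampling_rate samples per second (default 1e5, with the 5 kHz
#'   bandwidth emulated by a Gaussian edge kernel).
#' @param seed integer RNG seed.
#' @return object of class `sim_config`.
#' @examples
#' cfg <- sim_config(default_presets("WT"), c(WT = 10), duration_s = 5, seed = 1)
#' @export
sim_config <- function(presets = default_presets(),
                       concentrations = numeric(0),
                       duration_s = 60,
                       baseline_i0 = 100,
                       baseline_sigma = 2,
                       drift_amplitude = 0,
                       outlier_rate = 0,
                       temperature_C = 10,
                       voltage_mV = 160,
                       sampling_rate = 1e5,
                       seed = 1L) {
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (baseline_sigma <= 0) stop("baseline_sigma must be > 0", call. = FALSE)
  if (any(concentrations < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (length(concentrations) && is.null(names(concentrations)))
    stop("concentrations must be a named vector", call. = FALSE)
  if (length(presets) == 0 && any(concentrations > 0))
    stop("no presets supplied but nonzero concentrations requested", call. = FALSE)
  unknown <- setdiff(names(concentrations), names(presets))
  if (length(unknown))
    stop("concentration given for unknown class: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  stopifnot(sampling_rate > 0)
  structure(list(
    presets = presets, concentrations = concentrations,
    duration_s = duration_s, baseline_i0 = baseline_i0,
    baseline_sigma = baseline_sigma, drift_amplitude = drift_amplitude,
    outlier_rate = outlier_rate, temperature_C = temperature_C,
    voltage_mV = voltage_mV, sampling_rate = sampling_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Gaussian edge kernel emulating the 5 kHz low-pass characteristic:
# rectangular pulses convolved with a 0.07 ms sigma Gaussian.
.edge_kernel <- function(sampling_rate, sigma_ms = 0.07) {
  s <- sigma_ms * 1e-3 * sampling_rate
  half <- max(1L, ceiling(4 * s))
  k <- stats::dnorm(seq(-half, half), sd = s)
  k / sum(k)
}

# draw one dwell series (ms) for a preset at a given temperature
.draw_dwell_ms <- function(preset, n, temperature_C) {
  mu <- preset$dwell_log10_mean + log10(dwell_scale(preset, temperature_C))
  10^stats::rnorm(n, mu, preset$dwell_log10_sd)
}

# draw blockade ratios from a preset's mixture, with component bookkeeping
.draw_ratio <- function(preset, n) {
  rc <- preset$ratio_components
  comp <- sample.int(nrow(rc), n, replace = TRUE, prob = rc$weight)
  r <- stats::rnorm(n, rc$mean[comp], rc$sd[comp])
  bad <- r <= 0.01 | r >= 0.99
  while (any(bad)) {  # redraw the rare tail escapes; keeps ratio in (0,1)
    r[bad] <- stats::rnorm(sum(bad), rc$mean[comp[bad]], rc$sd[comp[bad]])
    bad <- r <= 0.01 | r >= 0.99
  }
  list(ratio = r, component = comp)
}

#' Simulate an ionic-current recording
#'
#' Builds an open-pore baseline (level + optional slow sinusoidal drift +
#' Gaussian white noise), then injects downward blockade events: arrivals
#' follow a Poisson process with rate
#' \eqn{\sum_c f_c \cdot [c]} (capture rate times concentration), depths are
#' drawn from each class's blockade-ratio mixture, and dwell times are
#' log-normal with the Eyring temperature scaling of [dwell_scale()].
#' Rectangular pulses are convolved with a Gaussian edge kernel (sigma
#' 0.07 ms) to emulate the 5 kHz recording bandwidth. Spurious
#' gating/outlier blockades (uniform depth, exponential dwell) are added at
#' `outlier_rate`.
#'
#' @param config a [sim_config()].
#' @return an object of class `trace`: list with `samples` (pA),
#'   `sampling_rate`, `voltage`, `temperature`, `i0_nominal`,
#'   `events_truth` (data frame `start`, `end`, `label`; 0-based half-open
#'   sample indices, analyte events only) and `outliers_truth` (same layout).
#' @examples
#' tr <- simulate_trace(sim_config(default_presets("WT"), c(WT = 10),
#'                                 duration_s = 2, seed = 42))
#' nrow(tr$events_truth)
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$sampling_rate
  n <- round(config$duration_s * fs)
  if (n < 10) stop("trace too short", call. = FALSE)

  # baseline: level + slow drift
  base <- rep(config$baseline_i0, n)
  if (config$drift_amplitude > 0) {
    period_s <- stats::runif(1, 20, 60)
    phase <- stats::runif(1, 0, 2 * pi)
    tt <- seq_len(n) / fs
    base <- base + config$drift_amplitude * sin(2 * pi * tt / period_s + phase)
  }

  # analyte arrivals: marked Poisson process with per-event dead time
  rates <- vapply(names(config$presets), function(cl) {
    conc <- if (cl %in% names(config$concentrations))
      config$concentrations[[cl]] else 0
    config$presets[[cl]]$capture_rate_per_uM * conc
  }, numeric(1))
  events <- list(); k <- 0L
  total <- sum(rates)
  if (total > 0) {
    t_cur <- 0
    repeat {
      t_cur <- t_cur + stats::rexp(1, total)
      if (t_cur >= config$duration_s) break
      cl <- sample(names(rates), 1, prob = rates / total)
      p <- config$presets[[cl]]
      dwell_ms <- .draw_dwell_ms(p, 1, config$temperature_C)
      ratio <- .draw_ratio(p, 1)$ratio
      s0 <- floor(t_cur * fs)
      e0 <- min(n, s0 + max(2L, round(dwell_ms * 1e-3 * fs)))
      k <- k + 1L
      events[[k]] <- list(start = s0, end = e0, label = cl, ratio = ratio)
      t_cur <- e0 / fs + 1 / fs  # occupied pore: next capture after release
    }
  }
  truth <- if (k) data.frame(
    start = vapply(events, `[[`, numeric(1), "start"),
    end = vapply(events, `[[`, numeric(1), "end"),
    label = vapply(events, `[[`, character(1), "label"),
    stringsAsFactors = FALSE
  ) else data.frame(start = numeric(0), end = numeric(0),
                    label = character(0), stringsAsFactors = FALSE)

  # spurious gating/outlier blockades dropped into free baseline stretches
  out_truth <- data.frame(start = numeric(0), end = numeric(0),
                          label = character(0), stringsAsFactors = FALSE)
  if (config$outlier_rate > 0) {
    n_out <- stats::rpois(1, config$outlier_rate * config$duration_s)
    if (n_out > 0) {
      os <- sort(stats::runif(n_out, 0, config$duration_s))
      od_ms <- stats::rexp(n_out, 1)  # mean 1 ms
      oratio <- stats::runif(n_out, 0.05, 0.95)
      s0 <- floor(os * fs)
      e0 <- pmin(n, s0 + pmax(2L, round(od_ms * 1e-3 * fs)))
      busy <- rep(FALSE, n)
      for (i in seq_len(nrow(truth)))
        busy[(truth$start[i] + 1):truth$end[i]] <- TRUE
      keep <- vapply(seq_len(n_out), function(i)
        !any(busy[(s0[i] + 1):e0[i]]), logical(1))
      keep <- keep & s0 < e0 - 1
      if (any(keep)) {
        out_truth <- data.frame(start = s0[keep], end = e0[keep],
                                label = "outlier", stringsAsFactors = FALSE)
        for (i in which(keep)) {
          k <- k + 1L
          events[[k]] <- list(start = s0[i], end = e0[i],
                              label = "outlier", ratio = oratio[i])
        }
      }
    }
  }

  # occupancy factor -> noiseless signal -> bandwidth kernel -> noise
  f <- rep(1, n)
  for (ev in events) f[(ev$start + 1):ev$end] <- ev$ratio
  signal <- base * f
  ker <- .edge_kernel(fs)
  sm <- stats::filter(signal, ker, sides = 2, circular = TRUE)
  samples <- as.numeric(sm) + stats::rnorm(n, 0, config$baseline_sigma)

  structure(list(
    samples = samples, sampling_rate = fs,
    voltage = config$voltage_mV, temperature = config$temperature_C,
    i0_nominal = config$baseline_i0,
    events_truth = truth, outliers_truth = out_truth
  ), class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("<trace> %.3g s at %g kHz (%d samples), %+d mV, %.1f degC\n",
              length(x$samples) / x$sampling_rate, x$sampling_rate / 1000,
              length(x$samples), x$voltage, x$temperature))
  cat(sprintf("  nominal I0 = %.1f pA; %d analyte truth events, %d outliers\n",
              x$i0_nominal, nrow(x$events_truth), nrow(x$outliers_truth)))
  invisible(x)
}

#' Simulate a labeled event feature table directly
#'
#' Shortcut generator that emits per-event features (blockade ratio,
#' duration, intra-event SD, skewness) straight from the emission models,
#' bypassing trace synthesis -- statistically matched to what
#' [detect_events()] + [extract_features()] recover from a simulated trace
#' of the same presets. Durations are rejection-sampled above the 0.50 ms
#' detectability cutoff, mirroring the event filter. The intra-event SD is
#' drawn from the sampling distribution of the SD of `n` Gaussian baseline
#' noise samples, and the skewness from its asymptotic null distribution
#' (variance 6/n); `n` is the number of interior samples implied by the
#' duration.
#'
#' @param config a [sim_config()] (presets, temperature, noise level and
#'   seed are used).
#' @param n_events events per class: a single count applied to every preset
#'   in `config`, or a named vector.
#' @return data frame with columns `ratio`, `duration_ms`, `sd`, `skewness`,
#'   `label`, `component` (mixture component index; secondary sialylated
#'   populations have `component == 2`).
#' @examples
#' cfg <- sim_config(default_presets(c("WT", "STn")), seed = 7)
#' ev <- simulate_event_table(cfg, n_events = 200)
#' table(ev$label)
#' @export
simulate_event_table <- function(config, n_events) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(names(n_events)))
    n_events <- stats::setNames(rep(n_events[1], length(config$presets)),
                                names(config$presets))
  unknown <- setdiff(names(n_events), names(config$presets))
  if (length(unknown))
    stop("unknown class name: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (any(n_events < 1)) stop("n_events must be >= 1 per class", call. = FALSE)
  set.seed(config$seed)
  fs <- config$sampling_rate
  rows <- lapply(names(n_events), function(cl) {
    p <- config$presets[[cl]]
    m <- n_events[[cl]]
    dur <- numeric(0)
    while (length(dur) < m) {  # truncate below the 0.50 ms event filter
      d <- .draw_dwell_ms(p, 2 * m, config$temperature_C)
      dur <- c(dur, d[d >= 0.50])
    }
    dur <- dur[seq_len(m)]
    rr <- .draw_ratio(p, m)
    # interior sample count mirroring detection: refined extent adds about
    # 0.24 ms of smoothed edge, and the trim removes max(10%, 0.35 ms) per side
    len <- (dur + 0.24) * 1e-3 * fs
    trim <- pmax(floor(0.10 * len), round(0.35e-3 * fs))
    nin <- pmax(3L, as.integer(round(len - 2 * trim)))
    sdv <- config$baseline_sigma * sqrt(stats::rchisq(m, nin - 1) / (nin - 1))
    skw <- stats::rnorm(m, 0, sqrt(6 / nin))
    data.frame(ratio = rr$ratio, duration_ms = dur, sd = sdv,
               skewness = skw, label = cl, component = rr$component,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
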