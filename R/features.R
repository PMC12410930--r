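#' Population (biased) skewness
#'
#' Third standardized moment with denominators `n` (not `n - 1`):
#' \deqn{g_1 = \frac{\frac1n\sum_i (x_i-\bar x)^3}
#'                  {[\frac1n\sum_i (x_i-\bar x)^2]^{3/2}}.}
#' A zero-variance input is degenerate: the value is reported as 0 and the
#' returned scalar carries the attribute `degenerate = TRUE`.
#'
#' @param x numeric vector, length >= 3.
#' @return scalar skewness (affine-invariant under positive scaling).
#' @examples
#' event_skewness(c(1, 2, 3))      # symmetric: 0
#' event_skewness(c(0, 0, 0, 1))   # 2/sqrt(3)
#' @export
event_skewness <- function(x) {
  if (length(x) < 3) stop("need at least 3 samples", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(structure(0, degenerate = TRUE))
  m3 <- mean((x - m)^3)
  m3 / m2^1.5
}

#' Extract the per-event feature vector
#'
#' Computes, for every detected event, the four features forming the
#' classifier feature matrix: blockade ratio I/I0, duration (ms),
#' intra-event current SD (pA), and skewness. SD and skewness are computed
#' on the same edge-trimmed interior samples used for the event mean
#' current; a normalized SD (`sd / i0`, dimensionless) is also reported so
#' that results do not depend on the absolute pore conductance. Events with
#' fewer than 3 interior samples or zero interior variance get `degenerate
#' = TRUE` with SD/skewness of 0.
#'
#' @param events an `event_table` from [detect_events()].
#' @param trace the `trace` the events were detected in.
#' @param edge_trim interior trim fraction; use the same value as in
#'   detection (default 0.10).
#' @param edge_guard_ms lower floor on the trimmed margin, ms (default
#'   0.35); match the detection setting.
#' @return data frame of class `feature_table`: `ratio`, `duration_ms`,
#'   `sd`, `sd_norm`, `skewness`, `degenerate` plus the event boundary
#'   columns. Row count always equals `nrow(events)`.
#' @examples
#' tr <- simulate_trace(sim_config(default_presets("WT"), c(WT = 20),
#'                                 duration_s = 2, seed = 3))
#' ev <- detect_events(tr, fit_baseline(tr, window_s = 2))
#' head(extract_features(ev, tr))
#' @export
extract_features <- function(events, trace, edge_trim = 0.10,
                             edge_guard_ms = 0.35) {
  stopifnot(inherits(trace, "trace"))
  n <- length(trace$samples)
  if (nrow(events) && (min(events$start_index) < 0 || max(events$end_index) > n))
    stop("event indices outside trace", call. = FALSE)
  rows <- lapply(seq_len(nrow(events)), function(i) {
    s <- events$start_index[i] + 1L  # to 1-based inclusive
    e <- events$end_index[i]
    len <- e - s + 1L
    trim <- max(floor(edge_trim * len),
                round(edge_guard_ms * 1e-3 * trace$sampling_rate))
    si <- s + trim; ei <- e - trim
    if (ei - si + 1L < 3L) {
      third <- max(1L, len %/% 3L)
      si <- s + third; ei <- e - third
      if (ei < si) { si <- s; ei <- e }
    }
    seg <- trace$samples[si:ei]
    if (length(seg) < 3) {
      sdv <- 0; skw <- 0; deg <- TRUE
    } else {
      sdv <- stats::sd(seg)
      if (sdv == 0) { skw <- 0; deg <- TRUE }
      else { skw <- as.numeric(event_skewness(seg)); deg <- FALSE }
    }
    data.frame(ratio = events$ratio[i], duration_ms = events$duration_ms[i],
               sd = sdv, sd_norm = sdv / events$i0_pA[i], skewness = skw,
               degenerate = deg, start_index = events$start_index[i],
               end_index = events$end_index[i])
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ratio = numeric(0), duration_ms = numeric(0), sd = numeric(0),
               sd_norm = numeric(0), skewness = numeric(0),
               degenerate = logical(0), start_index = integer(0),
               end_index = integer(0))
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}
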