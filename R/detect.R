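#' Estimate the open-pore baseline per segment
#'
#' Splits the trace into consecutive windows and, per window, fits a
#' Gaussian to the all-points current histogram restricted to the upper
#' (open-pore) mode, so that blockade samples do not bias the estimate.
#' The segmentation tracks slow baseline drift; downstream thresholds use
#' the open-pore level interpolated linearly between segment centers.
#'
#' @param trace a `trace` object (see [simulate_trace()] / [read_trace_csv()]).
#' @param window_s segment length, seconds; every segment must contain at
#'   least 1000 samples.
#' @return object of class `baseline_fit`: a data frame with one row per
#'   segment (`start`, `end` 0-based half-open sample indices, `i0`,
#'   `sigma`, both pA).
#' @examples
#' tr <- simulate_trace(sim_config(duration_s = 2, seed = 1))
#' fit_baseline(tr, window_s = 1)
#' @export
fit_baseline <- function(trace, window_s = 10) {
  stopifnot(inherits(trace, "trace"))
  x <- trace$samples
  n <- length(x)
  fs <- trace$sampling_rate
  w <- round(window_s * fs)
  if (w < 1000) stop("baseline window must contain >= 1000 samples", call. = FALSE)
  starts <- seq(1L, n, by = w)
  # fold a short trailing remnant into the final full window
  if (length(starts) > 1 && n - starts[length(starts)] + 1 < w / 2)
    starts <- starts[-length(starts)]
  segs <- lapply(seq_along(starts), function(i) {
    s <- starts[i]
    e <- if (i < length(starts)) starts[i + 1] - 1L else n
    seg <- x[s:e]
    est <- .fit_upper_mode(seg)
    data.frame(start = s - 1L, end = e, i0 = est$i0, sigma = est$sigma)
  })
  out <- do.call(rbind, segs)
  attr(out, "sampling_rate") <- fs
  attr(out, "n_samples") <- n
  class(out) <- c("baseline_fit", "data.frame")
  out
}

# Gaussian fit of the open-pore (upper) mode of an all-points histogram.
.fit_upper_mode <- function(seg) {
  if (stats::sd(seg) == 0) {
    warning("degenerate baseline: zero variance; sigma floored at 1e-6 pA")
    return(list(i0 = seg[1], sigma = 1e-6))
  }
  h <- graphics::hist(seg, breaks = "FD", plot = FALSE)
  cnt <- h$counts; mid <- h$mids
  # local maxima with substantial mass; the open pore is the upper one
  loc <- which(cnt >= c(-Inf, cnt[-length(cnt)]) &
               cnt >= c(cnt[-1], -Inf) & cnt >= 0.2 * max(cnt))
  if (!length(loc)) stop("no resolvable open-pore mode", call. = FALSE)
  peak <- loc[which.max(mid[loc])]
  # half-max width around the chosen mode -> rough sigma
  half <- cnt[peak] / 2
  lo <- peak; while (lo > 1 && cnt[lo - 1] >= half) lo <- lo - 1
  hi <- peak; while (hi < length(cnt) && cnt[hi + 1] >= half) hi <- hi + 1
  s0 <- max((mid[hi] - mid[lo]) / 2.355, diff(mid[1:2]))
  keep <- seg > mid[peak] - 4 * s0 & seg < mid[peak] + 4 * s0
  if (sum(keep) < 100) stop("no resolvable open-pore mode", call. = FALSE)
  sub <- seg[keep]
  # least-squares Gaussian on the restricted histogram; moment fallback
  hh <- graphics::hist(sub, breaks = "FD", plot = FALSE)
  df <- data.frame(xm = hh$mids, y = hh$counts)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(xm - mu)^2 / (2 * sg^2)), data = df,
                      start = list(A = max(df$y), mu = mean(sub), sg = stats::sd(sub)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    list(i0 = mean(sub), sigma = stats::sd(sub))
  } else {
    cf <- stats::coef(fit)
    list(i0 = unname(cf["mu"]), sigma = abs(unname(cf["sg"])))
  }
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("<baseline_fit> %d segment(s)\n", nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

# per-sample i0 / sigma by linear interpolation between segment centers
.baseline_track <- function(baselines, n) {
  ctr <- (baselines$start + baselines$end) / 2  # 0-based center
  if (nrow(baselines) == 1) {
    list(i0 = rep(baselines$i0, n), sigma = rep(baselines$sigma, n))
  } else {
    idx <- seq_len(n) - 0.5
    list(i0 = stats::approx(ctr, baselines$i0, idx, rule = 2)$y,
         sigma = stats::approx(ctr, baselines$sigma, idx, rule = 2)$y)
  }
}

#' Detect blockade events by baseline thresholding
#'
#' An event exists where the current drops below
#' \eqn{I_0 - k_\sigma\,\sigma} (default 5 sigma). Its extent is then
#' refined outward to the nearest crossings of \eqn{I_0 - 1\sigma}, so that
#' the bandwidth-smoothed edges are included in the reported duration: the
#' 5-sigma rule decides existence, the 1-sigma rule decides extent. The
#' minimum-duration filter (default 0.50 ms) is applied to the
#' threshold-crossing core of the event, so that injected events shorter
#' than the cutoff are excluded regardless of edge smoothing. Upward
#' excursions are ignored (the threshold is one-sided).
#'
#' `i_mean` is the mean of the samples strictly inside the refined extent
#' after trimming `edge_trim` of the length on each side, and the blockade
#' ratio is `i_mean` over the interpolated open-pore level at the event
#' midpoint.
#'
#' @param trace a `trace` object.
#' @param baselines a `baseline_fit` from [fit_baseline()].
#' @param k_sigma existence threshold multiplier (default 5).
#' @param min_duration_ms minimum core duration, ms (default 0.50).
#' @param refine_sigma extent threshold multiplier (default 1).
#' @param edge_trim fraction of the event length trimmed from each side
#'   before averaging (default 0.10).
#' @param edge_guard_ms lower floor on the trimmed margin, ms (default
#'   0.35, about five edge-kernel sigmas at the 5 kHz bandwidth), so that
#'   band-limited edge samples never leak into the interior of short
#'   events.
#' @return object of class `event_table`: data frame with columns
#'   `start_index`, `end_index` (0-based half-open, refined extent),
#'   `duration_ms` (refined), `core_duration_ms`, `i_mean_pA`, `i0_pA`,
#'   `sigma_pA`, `ratio`.
#' @examples
#' tr <- simulate_trace(sim_config(default_presets("WT"), c(WT = 20),
#'                                 duration_s = 2, seed = 3))
#' ev <- detect_events(tr, fit_baseline(tr, window_s = 2))
#' head(ev)
#' @export
detect_events <- function(trace, baselines, k_sigma = 5,
                          min_duration_ms = 0.50, refine_sigma = 1,
                          edge_trim = 0.10, edge_guard_ms = 0.35) {
  stopifnot(inherits(trace, "trace"))
  if (!inherits(baselines, "baseline_fit") || nrow(baselines) == 0)
    stop("baselines must be a non-empty baseline_fit", call. = FALSE)
  x <- trace$samples
  n <- length(x)
  fs <- trace$sampling_rate
  bt <- .baseline_track(baselines, n)
  below <- x < bt$i0 - k_sigma * bt$sigma
  empty <- data.frame(start_index = integer(0), end_index = integer(0),
                      duration_ms = numeric(0), core_duration_ms = numeric(0),
                      i_mean_pA = numeric(0), i0_pA = numeric(0),
                      sigma_pA = numeric(0), ratio = numeric(0))
  finish <- function(df) {
    attr(df, "sampling_rate") <- fs
    attr(df, "k_sigma") <- k_sigma
    attr(df, "min_duration_ms") <- min_duration_ms
    class(df) <- c("event_table", "data.frame")
    df
  }
  if (!any(below)) return(finish(empty))

  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cs <- starts[r$values]; ce <- ends[r$values]  # 1-based inclusive cores

  # refine extent to the nearest refine_sigma crossings
  above1 <- x >= bt$i0 - refine_sigma * bt$sigma
  idx <- seq_len(n)
  last_above <- cummax(ifelse(above1, idx, 0L))
  la_rev <- cummax(ifelse(rev(above1), idx, 0L))
  next_above <- rev(ifelse(la_rev > 0L, n + 1L - la_rev, n + 1L))
  rs <- ifelse(cs > 1L, last_above[pmax(cs - 1L, 1L)] + 1L, 1L)
  rs[cs == 1L] <- 1L
  re <- ifelse(ce < n, next_above[pmin(ce + 1L, n)] - 1L, n)
  re[ce == n] <- n

  # merge refined intervals that touch or overlap
  o <- order(rs)
  rs <- rs[o]; re <- re[o]
  m_rs <- rs[1]; m_re <- re[1]
  for (i in seq_along(rs)[-1]) {
    if (rs[i] <= m_re[length(m_re)] + 1L) {
      m_re[length(m_re)] <- max(m_re[length(m_re)], re[i])
    } else {
      m_rs <- c(m_rs, rs[i]); m_re <- c(m_re, re[i])
    }
  }

  rows <- lapply(seq_along(m_rs), function(i) {
    s <- m_rs[i]; e <- m_re[i]
    core_n <- sum(below[s:e])
    core_ms <- core_n / fs * 1e3
    if (core_ms < min_duration_ms) return(NULL)
    len <- e - s + 1L
    trim <- max(floor(edge_trim * len), round(edge_guard_ms * 1e-3 * fs))
    si <- s + trim; ei <- e - trim
    if (ei - si + 1L < 3L) {  # very short event: keep the central third
      third <- max(1L, len %/% 3L)
      si <- s + third; ei <- e - third
      if (ei < si) { si <- s; ei <- e }
    }
    im <- mean(x[si:ei])
    mid <- (s + e) %/% 2L
    i0 <- bt$i0[mid]; sg <- bt$sigma[mid]
    ratio <- im / i0
    if (!(ratio > 0 && ratio < 1)) return(NULL)
    data.frame(start_index = s - 1L, end_index = e,
               duration_ms = len / fs * 1e3, core_duration_ms = core_ms,
               i_mean_pA = im, i0_pA = i0, sigma_pA = sg, ratio = ratio)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  finish(out)
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d event(s), threshold I0 - %g sigma, min %g ms\n",
              nrow(x), attr(x, "k_sigma"), attr(x, "min_duration_ms")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Signal-to-noise ratio of an event population
#'
#' Mean blockade amplitude \eqn{I_0 - I} divided by the baseline SD.
#'
#' @param events an `event_table` (needs `i0_pA`, `i_mean_pA`).
#' @param baseline a `baseline_fit`; its mean segment sigma is the noise
#'   scale.
#' @return dimensionless SNR.
#' @export
snr <- function(events, baseline) {
  if (nrow(events) < 1) stop("need at least one event", call. = FALSE)
  sg <- mean(baseline$sigma)
  if (sg <= 0) stop("baseline sigma must be > 0", call. = FALSE)
  mean(events$i0_pA - events$i_mean_pA) / sg
}
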