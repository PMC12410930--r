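test_that("baseline fit recovers known level and noise", {
  tr <- simulate_trace(sim_config(duration_s = 2, baseline_i0 = 100,
                                  baseline_sigma = 2, seed = 1))
  b <- fit_baseline(tr, window_s = 2)
  expect_lt(abs(b$i0 - 100), 0.1)
  expect_lt(abs(b$sigma - 2) / 2, 0.10)
  # segments tile the trace
  expect_equal(b$start[1], 0)
  expect_equal(b$end[nrow(b)], length(tr$samples))
})

test_that("deep blockades do not bias the open-pore estimate", {
  # ~17% of samples in deep blockades; the upper-mode restriction
  # must keep i0 at the true open-pore level
  cfg <- sim_config(default_presets("STF"), c(STF = 200), duration_s = 2,
                    seed = 2)
  tr <- simulate_trace(cfg)
  occ <- sum(tr$events_truth$end - tr$events_truth$start) / length(tr$samples)
  expect_gt(occ, 0.10)
  b <- fit_baseline(tr, window_s = 2)
  expect_lt(abs(b$i0 - 100), 0.15)
  expect_lt(abs(b$sigma - 2) / 2, 0.10)
})

test_that("a constant trace yields the documented floored sigma", {
  tr <- structure(list(samples = rep(100, 2e5), sampling_rate = 1e5,
                       voltage = 160, temperature = 10, i0_nominal = 100,
                       events_truth = data.frame(), outliers_truth = data.frame()),
                  class = "trace")
  expect_warning(b <- fit_baseline(tr, window_s = 2), "degenerate")
  expect_equal(b$sigma, 1e-6)
})

test_that("a single injected event is recovered with its depth", {
  tr <- make_manual_trace(list(list(start = 50000, len = 200, ratio = 0.4)),
                          seed = 3)
  ev <- detect_events(tr, fit_baseline(tr, window_s = 1))
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$ratio - 0.4), 0.01)
  # the 1-sigma extent refinement includes the band-limited edges, adding
  # a bounded positive margin to the 2 ms rectangular truth
  expect_gte(ev$duration_ms, 2.0)
  expect_lte(ev$duration_ms, 2.4)
  expect_lt(abs(ev$core_duration_ms - 2), 0.25)
})

test_that("events shorter than the minimum duration are excluded", {
  evs <- list(list(start = 20000, len = 30, ratio = 0.4),    # 0.30 ms
              list(start = 50000, len = 35, ratio = 0.4),    # 0.35 ms
              list(start = 80000, len = 25, ratio = 0.4))    # 0.25 ms
  tr <- make_manual_trace(evs, seed = 4)
  ev <- detect_events(tr, fit_baseline(tr, window_s = 1))
  expect_equal(nrow(ev), 0)
  # the same events pass with the filter disabled
  ev2 <- detect_events(tr, fit_baseline(tr, window_s = 1),
                       min_duration_ms = 0.05)
  expect_equal(nrow(ev2), 3)
})

test_that("a pure-baseline trace produces no retained events", {
  # at 5 sigma the Gaussian tail admits ~P(z< -5)*n threshold crossings,
  # all far below the 0.50 ms duration filter
  tr <- simulate_trace(sim_config(duration_s = 60, seed = 5))
  ev <- detect_events(tr, fit_baseline(tr))
  expect_equal(nrow(ev), 0)
})

test_that("supra-threshold events are recalled with no overlaps", {
  cfg <- sim_config(default_presets("WT"), c(WT = 50), duration_s = 20,
                    seed = 9)
  tr <- simulate_trace(cfg)
  ev <- detect_events(tr, fit_baseline(tr))
  truth <- tr$events_truth
  truth <- truth[(truth$end - truth$start) >= 100, ]  # > 1 ms, depth ~ 27 sigma
  hit <- vapply(seq_len(nrow(truth)), function(i)
    any(ev$start_index < truth$end[i] & ev$end_index > truth$start[i]),
    logical(1))
  expect_gte(mean(hit), 0.95)
  expect_true(all(diff(ev$start_index) > 0))
  expect_true(all(ev$start_index[-1] >= ev$end_index[-nrow(ev)]))
  # re-running detection is bit-identical
  expect_identical(ev, detect_events(tr, fit_baseline(tr)))
})

test_that("detection tracks a drifting baseline", {
  cfg <- sim_config(default_presets("WT"), c(WT = 40), duration_s = 20,
                    drift_amplitude = 3, seed = 10)
  tr <- simulate_trace(cfg)
  ev <- detect_events(tr, fit_baseline(tr, window_s = 2))
  ft <- extract_features(ev, tr)
  expect_gt(nrow(ft), 50)
  expect_lt(abs(mean(ft$ratio) - 0.45), 0.01)
})

test_that("detect_events requires a usable baseline", {
  tr <- simulate_trace(sim_config(duration_s = 1, seed = 1))
  b <- fit_baseline(tr, window_s = 1)
  expect_error(detect_events(tr, b[0, ]), "baseline")
})

test_that("snr is amplitude over baseline noise", {
  evs <- lapply(seq(10000, 180000, by = 20000),
                function(s) list(start = s, len = 300, ratio = 0.4))
  tr <- make_manual_trace(evs, duration_s = 2, sigma = 3.47, seed = 12)
  b <- fit_baseline(tr, window_s = 2)
  e <- detect_events(tr, b)
  # (100 - 40) / 3.47 = 17.3
  expect_equal(snr(e, b), 17.3, tolerance = 0.02)
  # zero amplitude -> zero; doubling sigma halves the ratio
  e0 <- e; e0$i_mean_pA <- e0$i0_pA
  expect_equal(snr(e0, b), 0)
  b2 <- b; b2$sigma <- 2 * b$sigma
  expect_equal(snr(e, b2), snr(e, b) / 2)
  b3 <- b; b3$sigma <- 0
  expect_error(snr(e, b3), "sigma")
  expect_error(snr(e[0, ], b), "at least one")
})
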