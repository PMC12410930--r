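test_that("pure-baseline simulation has no events and the right level", {
  cfg <- sim_config(duration_s = 2, baseline_i0 = 100, baseline_sigma = 2,
                    drift_amplitude = 0, outlier_rate = 0, seed = 1)
  tr <- simulate_trace(cfg)
  expect_equal(nrow(tr$events_truth), 0)
  n <- length(tr$samples)
  expect_lt(abs(mean(tr$samples) - 100), 3 * 2 / sqrt(n))
})

test_that("simulation is bit-reproducible for a fixed config and seed", {
  cfg <- sim_config(default_presets("WT"), c(WT = 20), duration_s = 2,
                    outlier_rate = 1, drift_amplitude = 1, seed = 7)
  t1 <- simulate_trace(cfg)
  t2 <- simulate_trace(cfg)
  expect_identical(t1$samples, t2$samples)
  expect_identical(t1$events_truth, t2$events_truth)
  e1 <- simulate_event_table(cfg, c(WT = 50))
  e2 <- simulate_event_table(cfg, c(WT = 50))
  expect_identical(e1, e2)
})

test_that("event arrivals follow the configured Poisson rate", {
  # lambda = duration x concentration x capture rate
  p <- default_presets("WT")
  lam <- 60 * 10 * p$WT$capture_rate_per_uM
  cfg <- sim_config(p, c(WT = 10), duration_s = 60, seed = 42)
  n_ev <- nrow(simulate_trace(cfg)$events_truth)
  expect_lt(abs(n_ev - lam), 3 * sqrt(lam))
})

test_that("arrival counts are Poisson-dispersed across seeds", {
  p <- default_presets("TF")
  lam <- 10 * 5 * p$TF$capture_rate_per_uM
  counts <- vapply(1:40, function(s) {
    cfg <- sim_config(p, c(TF = 5), duration_s = 10, seed = 9000 + s)
    nrow(simulate_trace(cfg)$events_truth)
  }, numeric(1))
  expect_lt(abs(mean(counts) - lam), 3 * sqrt(lam / 40))
  # chi-square dispersion test at alpha = 0.01 (two-sided)
  disp <- sum((counts - mean(counts))^2) / mean(counts)
  df <- length(counts) - 1
  expect_gt(disp, qchisq(0.005, df))
  expect_lt(disp, qchisq(0.995, df))
})

test_that("truth intervals are sorted, non-overlapping and half-open", {
  cfg <- sim_config(default_presets(), c(WT = 20, Tn = 20, STn = 20),
                    duration_s = 5, seed = 3)
  tt <- simulate_trace(cfg)$events_truth
  expect_true(all(diff(tt$start) > 0))
  expect_true(all(tt$end > tt$start))
  expect_true(all(tt$start[-1] >= tt$end[-nrow(tt)]))
})

test_that("config validation rejects bad inputs", {
  expect_error(sim_config(concentrations = c(WT = -1)), "concentrations")
  expect_error(sim_config(duration_s = 0), "duration_s")
  expect_error(sim_config(presets = list(), concentrations = c(WT = 1)),
               "no presets")
  cfg <- sim_config(default_presets("WT"), seed = 1)
  expect_error(simulate_event_table(cfg, c(Tn = 10)), "unknown class")
  expect_error(simulate_event_table(cfg, c(WT = 0)), ">= 1")
})

test_that("shortcut event tables match the emission presets", {
  cfg <- sim_config(default_presets(c("WT", "STn")), seed = 5)
  ev <- simulate_event_table(cfg, n_events = c(WT = 500, STn = 500))
  wt <- ev[ev$label == "WT", ]
  # mean I/I0 near the configured 0.45 peak
  expect_lt(abs(mean(wt$ratio) - 0.45), 3 * 0.02 / sqrt(500))
  # single event request -> one finite row
  one <- simulate_event_table(cfg, n_events = c(WT = 1))
  expect_equal(nrow(one), 1)
  expect_true(all(is.finite(unlist(one[, c("ratio", "duration_ms",
                                           "sd", "skewness")]))))
  # durations respect the 0.50 ms detectability filter
  expect_true(all(ev$duration_ms >= 0.50))
})

test_that("sialylated classes emit two blockade-ratio modes", {
  cfg <- sim_config(default_presets("STn"), seed = 6)
  x <- simulate_event_table(cfg, n_events = c(STn = 500))$ratio
  f2 <- fit_ratio_peak(x, n_components = 2)
  f1 <- fit_ratio_peak(x, n_components = 1)
  # two well-separated components, neither negligible, and the
  # two-component model clearly improves the histogram fit
  expect_false(attr(f2, "flagged"))
  expect_gt(abs(diff(f2$mean)), max(f2$sd))
  expect_gt(attr(f2, "r_squared"), attr(f1, "r_squared"))
})

test_that("shortcut features are distributed like trace-extracted ones", {
  # the same emission model must be seen whether events are generated
  # directly or recovered from a full synthetic recording
  for (cl in c("WT", "STn")) {
    conc <- stats::setNames(120, cl)
    cfg <- sim_config(default_presets(cl), conc, duration_s = 40,
                      seed = 30 + match(cl, GLYCO_CLASSES))
    tr <- simulate_trace(cfg)
    ft <- extract_features(detect_events(tr, fit_baseline(tr)), tr)
    sc <- simulate_event_table(
      sim_config(default_presets(cl), seed = 60 + match(cl, GLYCO_CLASSES)),
      stats::setNames(10000, cl))
    ks <- suppressWarnings(stats::ks.test(ft$ratio, sc$ratio))
    expect_gt(ks$p.value, 0.01)
  }
})
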