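# shared fixture builders (all synthetic, generated at test time)

# a trace with hand-placed rectangular blockades, bandwidth-smoothed and
# noised exactly like the simulator output
make_manual_trace <- function(events, duration_s = 1, i0 = 100, sigma = 2,
                              fs = 1e5, seed = 1) {
  set.seed(seed)
  n <- round(duration_s * fs)
  x <- rep(i0, n)
  for (ev in events) {
    s <- ev$start + 1L; e <- ev$start + ev$len
    x[s:e] <- i0 * ev$ratio
  }
  ker <- glycopore:::.edge_kernel(fs)
  x <- as.numeric(stats::filter(x, ker, sides = 2, circular = TRUE)) +
    rnorm(n, 0, sigma)
  structure(list(samples = x, sampling_rate = fs, voltage = 160,
                 temperature = 10, i0_nominal = i0,
                 events_truth = data.frame(
                   start = vapply(events, function(e) e$start, numeric(1)),
                   end = vapply(events, function(e) e$start + e$len, numeric(1)),
                   label = rep("manual", length(events))),
                 outliers_truth = data.frame(start = numeric(0),
                                             end = numeric(0),
                                             label = character(0))),
            class = "trace")
}

# 6-class dataset separable in every feature (means >= 5 SDs apart)
make_separable_features <- function(n_per_class = 60, seed = 1) {
  set.seed(seed)
  mk <- function(n, i) data.frame(
    sd = rnorm(n, i, 0.1), skewness = rnorm(n, i / 2, 0.08),
    duration_ms = 10^rnorm(n, 0.25 * i, 0.02), ratio = rnorm(n, 0.1 * i, 0.008))
  feats <- do.call(rbind, lapply(1:6, function(i) mk(n_per_class, i)))
  labs <- rep(c("WT", "Tn", "TF", "STn-1", "STF-1", "MR"), each = n_per_class)
  list(features = feats, labels = labs)
}

# independent brute-force evaluation of the population-skewness formula,
# written as literal sums (the oracle stays independent of event_skewness)
skewness_bruteforce <- function(x) {
  n <- length(x)
  xb <- sum(x) / n
  num <- sum((x - xb)^3) / n
  den <- (sum((x - xb)^2) / n)^(3 / 2)
  if (den == 0) 0 else num / den
}

# Eyring rate evaluated directly (oracle for kinetics round trips)
koff_direct <- function(T_K, dH_J, dS_J) {
  kB <- 1.380649e-23; h <- 6.62607015e-34; R <- 8.314
  (kB * T_K / h) * exp(dS_J / R - dH_J / (R * T_K))
}

# full pipeline: pure samples -> labeling -> classifier -> capture table ->
# mixture quantification (the 2:2:1:3:3 recovery experiment, scaled to
# ~350 training events per class)
run_mixture_experiment <- function(seed, n_target = 350, n_mix = 1000,
                                   cv_folds = 2) {
  presets <- default_presets()
  conc_pure <- c(WT = 10, Tn = 10, TF = 2, STn = 5, STF = 3)
  rates <- vapply(presets, function(p) p$capture_rate_per_uM, numeric(1))
  len_pure <- n_target / (rates * conc_pure[names(rates)])
  set.seed(seed)
  n_pure <- stats::setNames(
    rpois(5, rates * conc_pure[names(rates)] * len_pure), names(rates))
  pure_tables <- lapply(names(presets), function(cl) {
    cfg <- sim_config(presets[cl], seed = seed + match(cl, names(presets)))
    simulate_event_table(cfg, stats::setNames(n_pure[[cl]], cl))
  })
  names(pure_tables) <- names(presets)
  ts <- build_training_set(pure_tables, presets)
  ds <- glyco_dataset(ts$features, ts$labels, seed = seed)
  best <- select_model(train_bench(ds, seed = seed, families = "MLP",
                                   cv_folds = cv_folds))
  pure_pred <- lapply(names(presets), function(cl) {
    ft <- pure_tables[[cl]]
    da <- denoise(ft)
    pred <- rep("noise", nrow(ft))
    pred[da$retained] <- as.character(predict(best, ft[da$retained, ]))
    pred
  })
  names(pure_pred) <- names(presets)
  ctab <- capture_frequencies_from_pure(pure_pred, as.list(len_pure),
                                        as.list(conc_pure))
  conc_mix <- c(WT = 3, Tn = 3, TF = 1, STn = 2, STF = 2)  # 2:2:1:3:3
  len_mix <- n_mix / sum(rates * conc_mix[names(rates)])
  set.seed(seed + 50)
  n_mix_cl <- stats::setNames(
    rpois(5, rates * conc_mix[names(rates)] * len_mix), names(rates))
  mix <- do.call(rbind, lapply(names(presets), function(cl) {
    cfg <- sim_config(presets[cl], seed = seed + 60 + match(cl, names(presets)))
    simulate_event_table(cfg, stats::setNames(n_mix_cl[[cl]], cl))
  }))
  est <- analyze_mixture(mix[, c("ratio", "duration_ms", "sd", "skewness")],
                         best, ctab)
  truth <- conc_mix / sum(conc_mix)
  list(estimate = est, truth = truth,
       error = est$proportion[match(names(truth), est$class)] - truth,
       model = best, capture = ctab)
}
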