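test_that("denoising removes sparse contamination, keeps the population", {
  set.seed(3)
  ev <- data.frame(ratio = rnorm(500, 0.45, 0.02),
                   duration_ms = 10^rnorm(500, 0.6, 0.15))
  out <- data.frame(ratio = runif(100, 0.05, 0.95),
                    duration_ms = 10^runif(100, -0.3, 1.5))
  da <- denoise(rbind(ev, out))
  is_out <- c(rep(FALSE, 500), rep(TRUE, 100))
  expect_gte(mean(!da$retained[is_out]), 0.90)
  expect_lte(mean(!da$retained[!is_out]), 0.05)
})

test_that("clean event clouds are retained nearly entirely", {
  cfg <- sim_config(default_presets("WT"), seed = 200)
  ev <- simulate_event_table(cfg, c(WT = 500))
  da <- denoise(ev)
  expect_gte(mean(da$retained), 0.98)
  # two-population sialylated cloud also survives
  cfgS <- sim_config(default_presets("STn"), seed = 201)
  evS <- simulate_event_table(cfgS, c(STn = 400))
  expect_gte(mean(denoise(evS)$retained), 0.95)
})

test_that("degenerate clustering inputs raise informative errors", {
  cfg <- sim_config(default_presets("WT"), seed = 202)
  ev <- simulate_event_table(cfg, c(WT = 30))
  expect_error(denoise(ev, min_cluster_size = 100), "min_cluster_size")
})

test_that("denoising is deterministic and scale-invariant", {
  cfg <- sim_config(default_presets("Tn"), seed = 203)
  ev <- simulate_event_table(cfg, c(Tn = 300))
  d1 <- denoise(ev)
  d2 <- denoise(ev)
  expect_identical(d1$cluster_id, d2$cluster_id)
  # affine rescaling of the raw features does not change the partition
  # (the cluster plane is z-scored internally)
  ev2 <- ev
  ev2$ratio <- ev2$ratio * 7 + 0.1
  ev2$duration_ms <- ev2$duration_ms^2  # log10 -> affine map
  d3 <- denoise(ev2)
  expect_identical(d1$cluster_id, d3$cluster_id)
})

test_that("sialylated splitting recovers the two sub-populations", {
  cfg <- sim_config(default_presets("STn"), seed = 204)
  ev <- simulate_event_table(cfg, c(STn = 400))
  sp <- split_sialylated(ev, primary_peak = 0.18)
  m1 <- mean(ev$ratio[sp$subclass == 1])
  m2 <- mean(ev$ratio[sp$subclass == 2])
  expect_lt(abs(m1 - 0.18), 0.02)
  expect_lt(abs(m2 - 0.26), 0.02)
  # agreement with the generating mixture component
  expect_gt(mean((ev$component == 1) == (sp$subclass == 1)), 0.9)
  expect_false(attr(sp, "flagged"))
  # label-order invariance: permuting rows permutes the partition
  perm <- sample(nrow(ev))
  sp2 <- split_sialylated(ev[perm, ], primary_peak = 0.18)
  expect_equal(sp2$subclass, sp$subclass[perm])
})

test_that("splitting a unimodal cloud is flagged", {
  cfg <- sim_config(default_presets("WT"), seed = 205)
  ev <- simulate_event_table(cfg, c(WT = 300))
  sp <- split_sialylated(ev, primary_peak = 0.45)
  expect_true(attr(sp, "flagged"))
  expect_error(split_sialylated(ev[1:20, ], 0.45), ">= 100")
})

test_that("MR assignment merges exactly the secondary sub-populations", {
  cfgS <- sim_config(default_presets(c("STn", "STF")), seed = 206)
  evn <- simulate_event_table(cfgS, c(STn = 300))
  evf <- simulate_event_table(sim_config(default_presets("STF"), seed = 207),
                              c(STF = 300))
  spn <- split_sialylated(evn, 0.18)
  spf <- split_sialylated(evf, 0.10)
  mr <- assign_mr(spn, spf)
  expect_equal(mr$n_mr, sum(spn$subclass == 2) + sum(spf$subclass == 2))
  expect_equal(sum(mr$stn_labels == "STn-1"), sum(spn$subclass == 1))
  expect_setequal(unique(mr$stf_labels), c("STF-1", "MR"))
})

test_that("labeling partitions events exactly: retained + noise + MR", {
  presets <- default_presets()
  tables <- lapply(names(presets), function(cl) {
    cfg <- sim_config(presets[cl], seed = 210 + match(cl, names(presets)))
    simulate_event_table(cfg, stats::setNames(300, cl))
  })
  names(tables) <- names(presets)
  ts <- build_training_set(tables, presets)
  n_total <- sum(vapply(tables, nrow, numeric(1)))
  expect_equal(length(ts$labels) + sum(ts$n_noise), n_total)
  expect_equal(nrow(ts$features), length(ts$labels))
  expect_setequal(unique(ts$labels),
                  c("WT", "Tn", "TF", "STn-1", "STF-1", "MR"))
})
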