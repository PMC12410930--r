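# Event-cloud denoising and sub-population labeling.
#
# Clustering operates on the (I/I0, log10 duration) scatter plane -- the
# plane in which event populations are inspected -- with each axis z-scored
# so that neither dominates the metric (raw duration spans decades).

.cluster_plane <- function(features) {
  stopifnot(all(c("ratio", "duration_ms") %in% names(features)))
  scale(cbind(features$ratio, log10(features$duration_ms)))
}

#' Density-based denoising of an event cloud (HDBSCAN)
#'
#' Runs HDBSCAN on the scaled (I/I0, log10 duration) plane and marks
#' low-density points (gating artifacts, bilayer-interaction noise, stray
#' outliers) as noise. The retained set is the union of all non-noise
#' clusters, preserving the most clustered population. Both the
#' hierarchy construction and the excess-of-mass cluster selection are
#' deterministic: inputs are processed in event order and no randomness is
#' involved.
#'
#' @param features a `feature_table` or data frame with `ratio` and
#'   `duration_ms`.
#' @param min_cluster_size smallest cluster size kept; default 5% of the
#'   number of events (at least 5).
#' @param min_samples neighborhood size for core distances (default 10).
#' @param relative_density_min within each selected cluster, points whose
#'   detachment density is below this fraction of the cluster's median
#'   detachment density are noise (default 0.2); this prunes sparse
#'   contamination without eroding the population core.
#' @return object of class `cluster_assignment`: data frame with
#'   `event_id`, `cluster_id` (-1 for noise) and `retained`.
#' @examples
#' cfg <- sim_config(default_presets("WT"), seed = 5)
#' ev <- simulate_event_table(cfg, n_events = c(WT = 300))
#' table(denoise(ev)$retained)
#' @export
denoise <- function(features,
                    min_cluster_size = max(5L, ceiling(0.05 * nrow(features))),
                    min_samples = 10, relative_density_min = 0.2) {
  n <- nrow(features)
  if (min_cluster_size > n)
    stop("degenerate clustering: min_cluster_size (", min_cluster_size,
         ") exceeds the number of events (", n, ")", call. = FALSE)
  res <- .hdbscan(.cluster_plane(features), min_cluster_size, min_samples,
                  relative_density_min = relative_density_min)
  if (all(res$labels == -1L))
    stop("degenerate clustering: every event was classified as noise; ",
         "lower min_cluster_size / min_samples", call. = FALSE)
  out <- data.frame(event_id = seq_len(n), cluster_id = res$labels,
                    retained = res$labels != -1L)
  attr(out, "n_clusters") <- res$n_clusters
  attr(out, "min_cluster_size") <- min_cluster_size
  attr(out, "min_samples") <- min_samples
  class(out) <- c("cluster_assignment", "data.frame")
  out
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d events: %d retained in %d cluster(s), %d noise\n",
              nrow(x), sum(x$retained), attr(x, "n_clusters"),
              sum(!x$retained)))
  invisible(x)
}

#' Split a sialylated event population into its two sub-populations
#'
#' The sialylated peptides (STn, STF) produce two event populations in the
#' blockade-ratio/duration scatter. This splits one class's events into two
#' groups by agglomerative clustering (Ward linkage, 2 clusters) on the
#' scaled feature plane. Sub-population "1" is the cluster whose mean I/I0
#' lies closer to the class's primary fitted peak; "2" is the other. The
#' split is flagged as dubious when a one-component Gaussian model of the
#' blockade ratios beats a two-component one by BIC (unimodal input); the
#' split is still returned and the caller decides. The mean silhouette
#' width is attached as a diagnostic.
#'
#' @param features a `feature_table` of one sialylated class.
#' @param primary_peak the class's primary fitted I/I0 peak (e.g., 0.18 for
#'   STn, 0.10 for STF).
#' @return object of class `sial_split`: data frame with `event_id` and
#'   `subclass` (1 or 2); attributes `silhouette` and `flagged`.
#' @examples
#' cfg <- sim_config(default_presets("STn"), seed = 5)
#' ev <- simulate_event_table(cfg, n_events = c(STn = 300))
#' sp <- split_sialylated(ev, primary_peak = 0.18)
#' table(sp$subclass)
#' @export
split_sialylated <- function(features, primary_peak) {
  n <- nrow(features)
  if (n < 100) stop("need >= 100 events (2 x minimum fit size) to split",
                    call. = FALSE)
  X <- .cluster_plane(features)
  d <- stats::dist(X)
  hc <- stats::hclust(d, method = "ward.D2")
  grp <- stats::cutree(hc, k = 2)
  if (length(unique(grp)) < 2)
    stop("split failure: one cluster is empty", call. = FALSE)
  m1 <- mean(features$ratio[grp == 1])
  m2 <- mean(features$ratio[grp == 2])
  # "-1" is the sub-population at the primary peak
  primary_first <- abs(m1 - primary_peak) <= abs(m2 - primary_peak)
  sub <- if (primary_first) grp else 3L - grp
  sil <- mean(cluster::silhouette(grp, d)[, "sil_width"])
  bic <- mclust::mclustBIC(features$ratio, G = 1:2, modelNames = "V",
                           verbose = FALSE)
  best_g <- as.integer(sub(".*,", "", names(summary(bic))[1]))
  out <- data.frame(event_id = seq_len(n), subclass = sub)
  attr(out, "silhouette") <- sil
  attr(out, "flagged") <- best_g < 2
  class(out) <- c("sial_split", "data.frame")
  out
}

#' @export
print.sial_split <- function(x, ...) {
  cat(sprintf("<sial_split> %d events -> %d / %d; silhouette %.3f%s\n",
              nrow(x), sum(x$subclass == 1), sum(x$subclass == 2),
              attr(x, "silhouette"),
              if (isTRUE(attr(x, "flagged"))) " (flagged: weak separation)" else ""))
  invisible(x)
}

#' Merge the secondary sialylated sub-populations into the MR class
#'
#' The secondary sub-populations of STn and STF overlap substantially and
#' are merged into one catch-all class, the merging region (MR). MR events
#' are kept as a class for classifier training (6 classes in total) but are
#' ignored in all proportion statistics.
#'
#' @param stn_split,stf_split `sial_split` objects for the STn and STF
#'   event sets.
#' @return list with character vectors `stn_labels` (`"STn-1"` / `"MR"`),
#'   `stf_labels` (`"STF-1"` / `"MR"`), and the MR count `n_mr`.
#' @export
assign_mr <- function(stn_split, stf_split) {
  stopifnot(inherits(stn_split, "sial_split"), inherits(stf_split, "sial_split"))
  stn_labels <- ifelse(stn_split$subclass == 1L, "STn-1", "MR")
  stf_labels <- ifelse(stf_split$subclass == 1L, "STF-1", "MR")
  list(stn_labels = stn_labels, stf_labels = stf_labels,
       n_mr = sum(stn_labels == "MR") + sum(stf_labels == "MR"))
}
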