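# End-to-end composition helpers: pure-sample labeling, capture
# frequencies from classified pure runs, and mixture analysis.

#' Build the 6-class training set from pure-sample event tables
#'
#' Applies the standard labeling pipeline to per-class event feature
#' tables: HDBSCAN denoising per class, agglomerative 2-way splitting of
#' the sialylated classes, and relabeling of the secondary sub-populations
#' as MR. The result is the 6-class labeled set (WT, Tn, TF, STn-1, STF-1,
#' MR) used for classifier training; noise events are dropped and counted.
#'
#' @param pure_tables named list of feature tables, one per class; names
#'   must be in [GLYCO_CLASSES].
#' @param presets the presets the class peaks are read from (the dominant
#'   component mean anchors the "-1" sub-population).
#' @param ... passed to [denoise()].
#' @return list with `features` (row-bound retained events), `labels`
#'   (character), `source_class`, and per-class counts `n_noise`.
#' @export
build_training_set <- function(pure_tables, presets = default_presets(), ...) {
  stopifnot(all(names(pure_tables) %in% GLYCO_CLASSES))
  feats <- list(); labs <- list(); src <- list()
  n_noise <- stats::setNames(integer(length(pure_tables)), names(pure_tables))
  for (cl in names(pure_tables)) {
    ft <- as.data.frame(pure_tables[[cl]])
    da <- denoise(ft, ...)
    n_noise[cl] <- sum(!da$retained)
    kept <- ft[da$retained, , drop = FALSE]
    if (cl %in% c("STn", "STF")) {
      rc <- presets[[cl]]$ratio_components
      primary <- rc$mean[which.max(rc$weight)]
      sp <- split_sialylated(kept, primary_peak = primary)
      lab <- ifelse(sp$subclass == 1L, paste0(cl, "-1"), "MR")
    } else {
      lab <- rep(cl, nrow(kept))
    }
    feats[[cl]] <- kept; labs[[cl]] <- lab
    src[[cl]] <- rep(cl, nrow(kept))
  }
  list(features = do.call(rbind, feats), labels = unlist(labs, use.names = FALSE),
       source_class = unlist(src, use.names = FALSE), n_noise = n_noise)
}

#' Capture-frequency table from classified pure-sample runs
#'
#' For each pure-sample run, counts the events the classifier assigns to
#' that analyte's own primary label (`WT`, `Tn`, `TF`, `STn-1`, `STF-1`)
#' and divides by recording time and concentration. Estimating the
#' frequency from *classified* pure-sample events keeps the mixture
#' correction consistent: the same classification losses (MR assignment,
#' confusion, denoising) affect numerator and reference alike.
#'
#' @param pure_predictions named list of predicted label vectors, one per
#'   pure run (names = class).
#' @param length_s named recording lengths, s.
#' @param conc_uM named concentrations, micromolar.
#' @return a [capture_table()].
#' @export
capture_frequencies_from_pure <- function(pure_predictions, length_s, conc_uM) {
  cls <- names(pure_predictions)
  freq <- vapply(cls, function(cl) {
    own <- if (cl %in% c("STn", "STF")) paste0(cl, "-1") else cl
    n <- sum(as.character(pure_predictions[[cl]]) == own)
    estimate_capture_frequency(n, length_s[[cl]], conc_uM[[cl]])
  }, numeric(1))
  capture_table(cls, unname(freq),
                length_s = unname(unlist(length_s)[cls]),
                conc_uM = unname(unlist(conc_uM)[cls]))
}

#' Analyze a mixture event table end to end
#'
#' Denoises the mixture events, predicts a label per retained event with
#' the selected model, and converts the predicted counts into
#' capture-corrected molar proportions, excluding MR and noise.
#'
#' @param features mixture feature table.
#' @param report a `model_report` (see [select_model()]).
#' @param frequencies a [capture_table()].
#' @param denoise_first run [denoise()] before prediction (default TRUE).
#' @param ... passed to [denoise()].
#' @return a `mixture_estimate`; the per-event predictions (including
#'   `"noise"`) are attached as attribute `predictions`.
#' @export
analyze_mixture <- function(features, report, frequencies,
                            denoise_first = TRUE, ...) {
  features <- as.data.frame(features)
  pred_all <- rep("noise", nrow(features))
  if (denoise_first) {
    da <- denoise(features, ...)
    keep <- da$retained
  } else {
    keep <- rep(TRUE, nrow(features))
  }
  pred <- predict(report, features[keep, , drop = FALSE])
  pred_all[keep] <- as.character(pred)
  est <- quantify_mixture(pred_all[keep], frequencies)
  attr(est, "n_noise") <- sum(!keep)
  attr(est, "predictions") <- pred_all
  est
}
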