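#' Estimate per-class capture frequency from pure-sample recordings
#'
#' Capture frequency is the pure-sample observable used to convert
#' classified event counts into molar proportions: retained events per
#' second per micromolar. Multiple recordings of the same analyte may be
#' pooled; the estimate is then total counts over total
#' concentration-weighted time, i.e. the count-weighted estimate over the
#' summed recording time.
#'
#' @param n_events retained event count(s), one per recording.
#' @param length_s recording length(s), seconds.
#' @param concentration_uM analyte concentration(s), micromolar.
#' @return events per second per micromolar.
#' @examples
#' estimate_capture_frequency(600, 60, 10)  # 1 event/s/uM
#' @export
estimate_capture_frequency <- function(n_events, length_s, concentration_uM) {
  if (any(length_s <= 0)) stop("recording length must be > 0", call. = FALSE)
  if (any(concentration_uM <= 0)) stop("concentration must be > 0", call. = FALSE)
  stopifnot(length(n_events) == length(length_s),
            length(length_s) == length(concentration_uM))
  sum(n_events) / sum(length_s * concentration_uM)
}

#' Build a capture-frequency table
#'
#' @param class character vector of class names.
#' @param frequency events per second per micromolar, per class (> 0).
#' @param n_events,length_s,conc_uM optional provenance columns (the pure
#'   sample each frequency was estimated from).
#' @return data frame of class `capture_table`.
#' @export
capture_table <- function(class, frequency, n_events = NA, length_s = NA,
                          conc_uM = NA) {
  if (any(frequency <= 0)) stop("capture frequencies must be > 0", call. = FALSE)
  out <- data.frame(class = class, frequency = frequency,
                    n_events = n_events, length_s = length_s,
                    conc_uM = conc_uM, stringsAsFactors = FALSE)
  class(out) <- c("capture_table", "data.frame")
  out
}

#' Capture-frequency-corrected mixture quantification
#'
#' Converts classified event counts from a mixture recording into molar
#' proportions. Classes capture at different rates, so raw counts are
#' divided by the pure-sample capture frequency before normalizing:
#' \deqn{p_c = \frac{n_c / f_c}{\sum_{c'} n_{c'} / f_{c'}}.}
#' MR (merging-region) and noise predictions are excluded from both
#' numerator and denominator; the `STn-1` and `STF-1` counts stand for STn
#' and STF (their secondary events live in MR by construction). With all
#' frequencies equal, the corrected proportions reduce to raw count
#' fractions, and the result is invariant under uniform rescaling of the
#' frequencies.
#'
#' @param predicted character or factor vector of predicted per-event
#'   labels (levels may include `"MR"` and `"noise"`).
#' @param frequencies a [capture_table()]; must cover every non-MR class
#'   present in `predicted`. Rows named `STn`/`STF` also serve predictions
#'   labeled `STn-1`/`STF-1`.
#' @return object of class `mixture_estimate`: data frame with `class`,
#'   `n_predicted`, `frequency`, `proportion`; attributes `n_mr_ignored`,
#'   `n_noise`, `n_total_used`.
#' @examples
#' ct <- capture_table(c("WT", "Tn"), c(2, 1))
#' quantify_mixture(rep(c("WT", "Tn"), each = 100), ct)
#' @export
quantify_mixture <- function(predicted, frequencies) {
  predicted <- as.character(predicted)
  n_mr <- sum(predicted == "MR")
  n_noise <- sum(predicted == "noise")
  used <- predicted[!predicted %in% c("MR", "noise")]
  canon <- sub("-1$", "", used)  # STn-1 -> STn, STF-1 -> STF
  counts <- table(canon)
  missing <- setdiff(names(counts), frequencies$class)
  if (length(missing))
    stop("no capture frequency for predicted class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  f <- frequencies$frequency[match(names(counts), frequencies$class)]
  corr <- as.numeric(counts) / f
  prop <- corr / sum(corr)
  out <- data.frame(class = names(counts),
                    n_predicted = as.integer(counts),
                    frequency = f, proportion = prop,
                    stringsAsFactors = FALSE)
  attr(out, "n_mr_ignored") <- n_mr
  attr(out, "n_noise") <- n_noise
  attr(out, "n_total_used") <- length(used)
  class(out) <- c("mixture_estimate", "data.frame")
  out
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat(sprintf("<mixture_estimate> %d events used, %d MR ignored, %d noise\n",
              attr(x, "n_total_used"), attr(x, "n_mr_ignored"),
              attr(x, "n_noise")))
  df <- as.data.frame(x)
  df$proportion <- sprintf("%.3f", df$proportion)
  print.data.frame(df, row.names = FALSE, ...)
  invisible(x)
}
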