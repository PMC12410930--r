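# Trace and event interchange formats:
#  - CSV trace: columns time_s,current_pA (sampling rate inferred)
#  - float32 binary trace + plain-text sidecar (key: value metadata)
#  - TSV truth events: start,end,label (0-based half-open indices)
#  - TSV detected events: the event_table columns

#' Write / read a trace as CSV
#'
#' Two columns, `time_s` and `current_pA`. Metadata travels in a
#' `# key: value` comment header.
#'
#' @param trace a `trace` object.
#' @param path output file.
#' @return `read_trace_csv` returns a `trace` (without truth events).
#' @export
write_trace_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate: %g", trace$sampling_rate), con)
  writeLines(sprintf("# voltage_mV: %g", trace$voltage), con)
  writeLines(sprintf("# temperature_C: %g", trace$temperature), con)
  writeLines(sprintf("# i0_nominal_pA: %g", trace$i0_nominal), con)
  writeLines("time_s,current_pA", con)
  t <- (seq_along(trace$samples) - 1) / trace$sampling_rate
  writeLines(sprintf("%.6f,%.4f", t, trace$samples), con)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  hdr <- readLines(path, n = 10)
  meta <- hdr[startsWith(hdr, "#")]
  get <- function(key, default) {
    m <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (length(m)) as.numeric(sub(".*: *", "", m[1])) else default
  }
  df <- utils::read.csv(path, comment.char = "#")
  fs <- get("sampling_rate", 1 / stats::median(diff(df$time_s)))
  structure(list(
    samples = df$current_pA, sampling_rate = fs,
    voltage = get("voltage_mV", NA), temperature = get("temperature_C", NA),
    i0_nominal = get("i0_nominal_pA", stats::median(df$current_pA)),
    events_truth = data.frame(start = numeric(0), end = numeric(0),
                              label = character(0)),
    outliers_truth = data.frame(start = numeric(0), end = numeric(0),
                                label = character(0))
  ), class = "trace")
}

#' Write / read a trace as float32 binary with a text sidecar
#'
#' Samples go to `<prefix>.f32` (little-endian float32); metadata
#' (sampling rate, voltage, temperature, nominal I0) to `<prefix>.meta`.
#'
#' @param trace a `trace` object.
#' @param prefix output path prefix.
#' @export
write_trace_bin <- function(trace, prefix) {
  con <- file(paste0(prefix, ".f32"), "wb")
  writeBin(as.numeric(trace$samples), con, size = 4, endian = "little")
  close(con)
  writeLines(c(
    sprintf("sampling_rate: %g", trace$sampling_rate),
    sprintf("voltage_mV: %g", trace$voltage),
    sprintf("temperature_C: %g", trace$temperature),
    sprintf("i0_nominal_pA: %g", trace$i0_nominal)
  ), paste0(prefix, ".meta"))
  invisible(prefix)
}

#' @rdname write_trace_bin
#' @export
read_trace_bin <- function(prefix) {
  meta <- readLines(paste0(prefix, ".meta"))
  get <- function(key) {
    m <- grep(paste0("^", key, ":"), meta, value = TRUE)
    if (length(m)) as.numeric(sub(".*: *", "", m[1])) else NA_real_
  }
  fn <- paste0(prefix, ".f32")
  n <- file.info(fn)$size / 4
  con <- file(fn, "rb")
  x <- readBin(con, numeric(), n = n, size = 4, endian = "little")
  close(con)
  structure(list(
    samples = x, sampling_rate = get("sampling_rate"),
    voltage = get("voltage_mV"), temperature = get("temperature_C"),
    i0_nominal = get("i0_nominal_pA"),
    events_truth = data.frame(start = numeric(0), end = numeric(0),
                              label = character(0)),
    outliers_truth = data.frame(start = numeric(0), end = numeric(0),
                                label = character(0))
  ), class = "trace")
}

#' Write / read event tables as TSV
#'
#' @param events a data frame (`event_table`, `feature_table`, or truth
#'   events).
#' @param path file path.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
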