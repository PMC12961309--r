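#' Lead-field matrix
#'
#' Linear forward map from region-level source activity (mV) to EEG
#' channel voltages (uV). The lead field is treated as data: head-model
#' construction is out of scope.
#'
#' @param gain Channels x regions numeric matrix (uV per mV source).
#' @param channel_names Optional channel names; defaults to `"ch_1"`, ...
#' @return A `lead_field` object.
#' @export
lead_field <- function(gain, channel_names = NULL) {
  gain <- as.matrix(gain)
  if (!all(is.finite(gain)))
    stop("lead-field gain contains non-finite values", call. = FALSE)
  if (nrow(gain) < 1) stop("lead field needs >= 1 channel",
                           call. = FALSE)
  if (is.null(channel_names))
    channel_names <- paste0("ch_", seq_len(nrow(gain)))
  if (length(channel_names) != nrow(gain))
    stop("one channel name per lead-field row required", call. = FALSE)
  structure(list(gain = unname(gain),
                 channel_names = as.character(channel_names)),
            class = "lead_field")
}

#' EEG time series container
#'
#' @param time Strictly increasing, uniformly sampled time axis (s; 0 at
#'   stimulus onset).
#' @param data Channels x time numeric matrix (uV).
#' @param channel_names Optional channel names.
#' @return An `eeg_timeseries` object.
#' @export
eeg_timeseries <- function(time, data, channel_names = NULL) {
  data <- as.matrix(data)
  if (length(time) != ncol(data))
    stop("time axis (", length(time), ") and data columns (", ncol(data),
         ") do not match", call. = FALSE)
  if (length(time) > 1) {
    dts <- diff(time)
    if (any(dts <= 0) ||
        max(dts) - min(dts) > 1e-9 * max(abs(dts)))
      stop("time axis must be strictly increasing and uniform",
           call. = FALSE)
  }
  if (!all(is.finite(data)))
    stop("EEG data contains non-finite values", call. = FALSE)
  if (is.null(channel_names))
    channel_names <- paste0("ch_", seq_len(nrow(data)))
  structure(list(time = as.numeric(time), data = unname(data),
                 channel_names = as.character(channel_names)),
            class = "eeg_timeseries")
}

#' @export
print.eeg_timeseries <- function(x, ...) {
  cat("eeg_timeseries:", nrow(x$data), "channels x", ncol(x$data),
      "samples,", sprintf("t in [%.3f, %.3f] s\n", min(x$time),
                          max(x$time)))
  invisible(x)
}

#' Project source activity to EEG channels
#'
#' Multiplies the lead-field gain with the region x time PSP matrix;
#' with the (default) average reference the channel mean is subtracted
#' at every time point, as is standard before global-mean-field-power
#' computation.
#'
#' @param src A `source_activity` from [simulate_network()].
#' @param lf A [lead_field()] whose columns match the source regions.
#' @param reference `"average"` or `"none"`.
#' @return An [eeg_timeseries()].
#' @export
project <- function(src, lf, reference = c("average", "none")) {
  reference <- match.arg(reference)
  if (ncol(lf$gain) != nrow(src$psp))
    stop("lead field has ", ncol(lf$gain), " columns but source has ",
         nrow(src$psp), " regions", call. = FALSE)
  data <- lf$gain %*% src$psp
  if (reference == "average")
    data <- sweep(data, 2L, colMeans(data))
  eeg_timeseries(src$time, data, lf$channel_names)
}

#' Extract a stimulus-locked epoch
#'
#' Crops the recording to the half-open window `[start, end)` (s) and
#' optionally subtracts the per-channel mean over a baseline window.
#' At 1 kHz the window `(0, 0.3)` yields exactly 300 samples.
#'
#' @param eeg An [eeg_timeseries()].
#' @param window Numeric `c(start, end)` in s.
#' @param baseline Optional `c(start, end)` in s for baseline
#'   correction.
#' @return An [eeg_timeseries()] restricted to the window.
#' @export
extract_epoch <- function(eeg, window, baseline = NULL) {
  eps <- 1e-9
  sel <- eeg$time >= window[1] - eps & eeg$time < window[2] - eps
  if (!any(sel))
    stop("epoch window [", window[1], ", ", window[2],
         ") contains no samples", call. = FALSE)
  if (window[1] < min(eeg$time) - eps ||
      window[2] > max(eeg$time) + mean(diff(eeg$time)) + eps)
    stop("epoch window lies (partly) outside the recording",
         call. = FALSE)
  data <- eeg$data[, sel, drop = FALSE]
  if (!is.null(baseline)) {
    bsel <- eeg$time >= baseline[1] - eps & eeg$time < baseline[2] - eps
    if (!any(bsel))
      stop("baseline window contains no samples", call. = FALSE)
    data <- data - rowMeans(eeg$data[, bsel, drop = FALSE])
  }
  eeg_timeseries(eeg$time[sel], data, eeg$channel_names)
}

#' Write / read EEG epochs as CSV
#'
#' Long-format CSV with columns `time`, `channel`, `value` (uV).
#'
#' @param eeg An [eeg_timeseries()].
#' @param path Output file.
#' @return `eeg`, invisibly (writer); an `eeg_timeseries` (reader).
#' @export
write_eeg_csv <- function(eeg, path) {
  df <- data.frame(
    time = rep(eeg$time, each = nrow(eeg$data)),
    channel = rep(eeg$channel_names, times = ncol(eeg$data)),
    value = as.vector(eeg$data))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(eeg)
}

#' @rdname write_eeg_csv
#' @export
read_eeg_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c("numeric", "character",
                                             "numeric"))
  channels <- unique(df$channel)
  time <- unique(df$time)
  data <- matrix(df$value, nrow = length(channels),
                 ncol = length(time))
  eeg_timeseries(time, data, channels)
}
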