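# S3 containers for the signal types moving through the pipeline.  All
# constructors validate their invariants so downstream code can assume them.

#' Bilateral skin blood perfusion recording
#'
#' Container for simultaneously recorded left/right laser-Doppler perfusion
#' traces (perfusion units, PU).  The nominal hardware sampling rate is
#' 64 Hz.
#'
#' @param time Sample times in seconds, strictly increasing, spacing
#'   approximately `1/fs`.
#' @param left,right Perfusion traces (PU), same length as `time`, finite.
#' @param fs Sampling rate in Hz.
#' @param subject_id Subject label.
#' @param phase Recording phase, `"pre"` or `"post"` stimulus.
#' @return An object of class `perfusion_recording`.
#' @export
perfusion_recording <- function(time, left, right, fs,
                                subject_id = "s1", phase = c("pre", "post")) {
  phase <- match.arg(phase)
  fs <- check_number(fs, "fs", lower = 0, strict_lower = TRUE)
  n <- length(time)
  if (length(left) != n || length(right) != n)
    stop_data("time, left and right must have equal length")
  if (n < 2L) stop_data("a perfusion recording needs at least 2 samples")
  if (any(is.infinite(left)) || any(is.infinite(right)))
    stop_data("perfusion traces must not contain infinite values")
  # NA/NaN gaps are tolerated here so that preprocess_perfusion() can
  # interpolate them; the spectral estimators reject them.
  dt <- diff(time)
  if (any(dt <= 0)) stop_data("time must be strictly increasing")
  if (abs(median(dt) - 1 / fs) > 0.05 / fs)
    stop_data("median time step is inconsistent with fs")
  structure(
    list(time = as.numeric(time), left = as.numeric(left),
         right = as.numeric(right), fs = fs,
         subject_id = as.character(subject_id), phase = phase),
    class = "perfusion_recording")
}

#' @export
print.perfusion_recording <- function(x, ...) {
  cat(sprintf("<perfusion_recording> subject %s, phase %s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$phase, length(x$left), x$fs,
              length(x$left) / x$fs))
  invisible(x)
}

#' RR-interval series
#'
#' Ordered RR intervals (ms) with the cumulative onset time of each interval.
#'
#' @param rr RR intervals in milliseconds, all positive.
#' @param t Onset time of each interval in seconds (default: cumulative sum
#'   starting at 0). Must be non-decreasing.
#' @param subject_id Subject label.
#' @param phase `"pre"` or `"post"`.
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(rr, t = NULL, subject_id = "s1",
                      phase = c("pre", "post")) {
  phase <- match.arg(phase)
  rr <- as.numeric(rr)
  if (length(rr) == 0L) stop_data("rr must be non-empty")
  if (any(!is.finite(rr)) || any(rr <= 0))
    stop_data("all RR intervals must be positive and finite")
  if (is.null(t)) t <- c(0, cumsum(rr[-length(rr)])) / 1000
  if (length(t) != length(rr)) stop_data("t and rr must have equal length")
  if (any(diff(t) < 0)) stop_data("t must be non-decreasing")
  structure(list(rr = rr, t = as.numeric(t),
                 subject_id = as.character(subject_id), phase = phase),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> subject %s, phase %s: %d intervals, mean %.1f ms\n",
              x$subject_id, x$phase, length(x$rr), mean(x$rr)))
  invisible(x)
}

#' Multichannel electrogastrogram recording
#'
#' @param channels Numeric matrix, one column per channel (microvolts).
#' @param fs Sampling rate in Hz (nominal 1000 after down-sampling).
#' @param channel_labels Channel labels; default `ch1 ... chN`.
#' @param subject_id Subject label.
#' @param phase `"pre"` or `"post"`.
#' @return An object of class `egg_recording`.
#' @export
egg_recording <- function(channels, fs, channel_labels = NULL,
                          subject_id = "s1", phase = c("pre", "post")) {
  phase <- match.arg(phase)
  fs <- check_number(fs, "fs", lower = 0, strict_lower = TRUE)
  channels <- as.matrix(channels)
  if (!is.numeric(channels) || any(!is.finite(channels)))
    stop_data("EGG channels must be finite numeric")
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(ncol(channels)))
  if (length(channel_labels) != ncol(channels))
    stop_data("one label per channel required")
  colnames(channels) <- channel_labels
  structure(list(channels = channels, fs = fs,
                 channel_labels = channel_labels,
                 subject_id = as.character(subject_id), phase = phase),
            class = "egg_recording")
}

#' @export
print.egg_recording <- function(x, ...) {
  cat(sprintf("<egg_recording> subject %s, phase %s: %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$phase, ncol(x$channels), nrow(x$channels), x$fs))
  invisible(x)
}
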