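# Electrogastrogram spectral analysis: anti-aliased down-sampling, Hann-taper
# FFT power spectra, and dominant-frequency (DF) extraction in the gastric
# slow-wave band 0.033-0.066 Hz (2-4 cycles per minute).

#' Down-sample an EGG recording
#'
#' Applies a zero-phase anti-alias low-pass (8th-order Butterworth at 80% of
#' the new Nyquist, forward-backward) to every channel, then keeps every
#' q-th sample where `q = fs_in / fs_out` must be an integer.
#'
#' @param rec An [egg_recording()] at the original sampling rate.
#' @param fs_out Target sampling rate in Hz; must divide `rec$fs` exactly.
#' @return An [egg_recording()] at `fs_out` with
#'   `floor(n * fs_out / fs_in)` samples per channel.
#' @export
downsample_egg <- function(rec, fs_out) {
  stopifnot(inherits(rec, "egg_recording"))
  fs_out <- check_number(fs_out, "fs_out", lower = 0, strict_lower = TRUE)
  q <- rec$fs / fs_out
  if (abs(q - round(q)) > 1e-9)
    stop_parameter(sprintf("fs_in / fs_out = %g is not an integer", q))
  q <- as.integer(round(q))
  if (q == 1L) return(rec)
  bf <- signal::butter(8, 0.8 / q, type = "low")
  n <- nrow(rec$channels)
  pad <- min(n - 1L, 30L * q)  # odd reflection pad to tame edge transients
  keep <- pad + seq.int(1L, n, by = q)
  ch <- apply(rec$channels, 2, function(x) {
    xp <- c(2 * x[1] - rev(x[2:(pad + 1L)]), x,
            2 * x[n] - rev(x[(n - pad):(n - 1L)]))
    signal::filtfilt(bf, xp)[keep]
  })
  egg_recording(ch, fs_out, channel_labels = rec$channel_labels,
                subject_id = rec$subject_id, phase = rec$phase)
}

#' Per-channel EGG power spectrum
#'
#' For each channel: remove the mean, apply a Hann taper over the full
#' record, FFT, and form the one-sided power `|X_k|^2 / n` (doubled away
#' from DC and Nyquist) so that the summed one-sided power equals the
#' energy of the tapered signal (Parseval).  Frequency resolution is
#' `fs / n`; the record must be at least `min_duration_s` long so the
#' 0.033--0.066 Hz band is resolvable.
#'
#' @param rec An [egg_recording()].
#' @param min_duration_s Minimum record duration in seconds (default 300,
#'   i.e. at least 10 slow-wave cycles, resolution about 0.0033 Hz).
#' @return An object of class `egg_spectrum`: list with `freqs` (Hz) and
#'   `power` (matrix, one column per channel, microvolt^2).
#' @export
egg_power_spectrum <- function(rec, min_duration_s = 300) {
  stopifnot(inherits(rec, "egg_recording"))
  n <- nrow(rec$channels)
  if (n / rec$fs < min_duration_s)
    stop_estimator(sprintf(
      "record is %.0f s; at least %.0f s needed to resolve the slow-wave band",
      n / rec$fs, min_duration_s))
  w <- taper_window("hann", n)
  nf <- n %/% 2L + 1L
  pw <- apply(rec$channels, 2, function(x) {
    xw <- (x - mean(x)) * w
    p <- Mod(fft(xw)[seq_len(nf)])^2 / n
    scale <- rep(2, nf)
    scale[1] <- 1
    if (n %% 2L == 0L) scale[nf] <- 1
    p * scale
  })
  structure(list(freqs = (seq_len(nf) - 1) * rec$fs / n,
                 power = pw, fs = rec$fs,
                 channel_labels = rec$channel_labels,
                 subject_id = rec$subject_id, phase = rec$phase),
            class = "egg_spectrum")
}

#' @export
print.egg_spectrum <- function(x, ...) {
  cat(sprintf("<egg_spectrum> %d channels, %d bins, df = %.5f Hz\n",
              ncol(x$power), length(x$freqs), x$freqs[2] - x$freqs[1]))
  invisible(x)
}

#' EGG dominant frequency
#'
#' Per channel, DF is the in-band argmax of the power spectrum (ties broken
#' toward the lowest frequency).  The subject-level DF is the DF of the
#' channel whose in-band peak power is largest, i.e. the channel showing
#' the strongest slow-wave activity.
#'
#' @param spec An `egg_spectrum` from [egg_power_spectrum()].
#' @param band Analysis band in Hz (default the 2--4 cpm gastric band
#'   `c(0.033, 0.066)`), endpoints inclusive.
#' @return List with `df_per_channel` (Hz, named by channel),
#'   `peak_power_per_channel`, `subject_df` (Hz) and `subject_channel`.
#' @examples
#' cfg <- synth_config(seed = 3, duration_s = 300, fs_egg = 10, egg_df_cpm = 3)
#' spec <- egg_power_spectrum(generate_egg(cfg))
#' dominant_frequency(spec)$subject_df  # about 0.05 Hz
#' @export
dominant_frequency <- function(spec, band = c(0.033, 0.066)) {
  stopifnot(inherits(spec, "egg_spectrum"))
  band <- check_band(band)
  in_band <- spec$freqs >= band[1] & spec$freqs <= band[2]
  if (!any(in_band))
    stop_band("no spectral bin falls inside the requested band")
  f <- spec$freqs[in_band]
  p <- spec$power[in_band, , drop = FALSE]
  peak_idx <- apply(p, 2, which.max)  # first maximum = lowest freq on ties
  dfs <- f[peak_idx]
  peaks <- p[cbind(peak_idx, seq_len(ncol(p)))]
  names(dfs) <- names(peaks) <- spec$channel_labels
  best <- which.max(peaks)
  list(df_per_channel = dfs, peak_power_per_channel = peaks,
       subject_df = unname(dfs[best]),
       subject_channel = spec$channel_labels[best], band = band)
}
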