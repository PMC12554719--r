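# Seedable generators emulating the statistical structure the downstream
# analyses assume: a shared cardiac-band oscillator driving bilateral
# perfusion coherence, sinusoidally modulated RR series, gastric slow waves
# on 1/f noise, and cohorts with linearly coupled PF and autonomic indices.
# These are assumption-bearing stand-ins for hardware recordings, not
# biophysical simulations.

#' Configuration for the synthetic signal generators
#'
#' Collects every tunable parameter of the signal-level generators.  A fixed
#' seed makes each generator fully deterministic (byte-identical output).
#'
#' @param seed Integer seed; all randomness of a generator call flows from it.
#' @param duration_s Recording duration in seconds (> 0).
#' @param fs_perfusion Perfusion sampling rate in Hz (hardware nominal 64).
#' @param fs_egg EGG sampling rate in Hz (nominal 1000 after down-sampling).
#' @param pf_target Frequency of the shared cardiac oscillator in Hz, within
#'   the PF analysis band \[1.0, 1.5\].
#' @param shared_fraction Amplitude fraction of the shared oscillator in
#'   \[0, 1\]; controls the height of the bilateral coherence peak.  At 1 the
#'   two sides are equal up to a per-side gain; at 0 they are independent.
#' @param rsa_amplitude_ms Depth (ms) of the 0.25 Hz respiratory sinus
#'   arrhythmia modulation of RR.
#' @param lf_amplitude_ms Depth (ms) of the 0.1 Hz slow RR modulation.
#' @param mean_rr_ms Mean RR interval in ms (must lie in \[300, 2000\]).
#' @param jitter_ms Standard deviation (ms) of beat-to-beat Gaussian jitter.
#' @param egg_df_cpm Gastric slow-wave frequency in cycles per minute,
#'   within \[2, 4\] (i.e. 0.033--0.066 Hz).
#' @param egg_noise_amp Amplitude of the 1/f-like EGG noise relative to a
#'   unit slow wave.
#' @param n_channels_egg Number of EGG channels (default 8).
#' @return A validated list of class `synth_config`.
#' @examples
#' cfg <- synth_config(seed = 1, duration_s = 120, pf_target = 1.2)
#' rec <- generate_bilateral_perfusion(cfg)
#' @export
synth_config <- function(seed = 1L, duration_s = 300, fs_perfusion = 64,
                         fs_egg = 1000, pf_target = 1.25,
                         shared_fraction = 0.6, rsa_amplitude_ms = 40,
                         lf_amplitude_ms = 30, mean_rr_ms = 850,
                         jitter_ms = 5, egg_df_cpm = 3, egg_noise_amp = 0.5,
                         n_channels_egg = 8L) {
  cfg <- list(
    seed            = as.integer(check_number(seed, "seed")),
    duration_s      = check_number(duration_s, "duration_s", lower = 0,
                                   strict_lower = TRUE),
    fs_perfusion    = check_number(fs_perfusion, "fs_perfusion", lower = 0,
                                   strict_lower = TRUE),
    fs_egg          = check_number(fs_egg, "fs_egg", lower = 0,
                                   strict_lower = TRUE),
    pf_target       = check_number(pf_target, "pf_target", 1.0, 1.5),
    shared_fraction = check_number(shared_fraction, "shared_fraction", 0, 1),
    rsa_amplitude_ms = check_number(rsa_amplitude_ms, "rsa_amplitude_ms",
                                    lower = 0),
    lf_amplitude_ms = check_number(lf_amplitude_ms, "lf_amplitude_ms",
                                   lower = 0),
    mean_rr_ms      = check_number(mean_rr_ms, "mean_rr_ms", 300, 2000),
    jitter_ms       = check_number(jitter_ms, "jitter_ms", lower = 0),
    egg_df_cpm      = check_number(egg_df_cpm, "egg_df_cpm", 2, 4),
    egg_noise_amp   = check_number(egg_noise_amp, "egg_noise_amp", lower = 0),
    n_channels_egg  = as.integer(check_number(n_channels_egg,
                                              "n_channels_egg", lower = 1)))
  class(cfg) <- "synth_config"
  cfg
}

# Ornstein-Uhlenbeck path, exact AR(1) discretization; gives the slow
# amplitude/phase drift that keeps synthetic coherence below 1 in noise.
ou_path <- function(n, dt, tau = 10, sigma = 1) {
  a <- exp(-dt / tau)
  innov_sd <- sigma * sqrt(1 - a^2)
  e <- rnorm(n, 0, innov_sd)
  e[1] <- rnorm(1, 0, sigma)
  as.numeric(stats::filter(e, a, method = "recursive"))
}

# White noise band-passed to the physiological fluctuation range, unit SD.
bandlimited_noise <- function(n, fs, band = c(0.4, 6)) {
  hi <- min(band[2], 0.45 * fs)
  bf <- signal::butter(2, c(band[1], hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  x / max(sd(x), .Machine$double.eps)
}

#' Generate a bilateral perfusion recording
#'
#' Simulates simultaneously recorded left/right skin blood perfusion traces
#' as a mixture of one shared cardiac-band oscillator (sinusoid at
#' `pf_target` with slow Ornstein--Uhlenbeck amplitude and phase drift,
#' weight `shared_fraction`) and, with weight `1 - shared_fraction`,
#' per-side independent band-limited noise plus low-frequency myogenic
#' (about 0.1 Hz) and respiratory (about 0.3 Hz) components.  The design
#' gives a single tunable coherence peak at `pf_target`.
#'
#' @param cfg A [synth_config()].
#' @param subject_id,phase Labels stored on the recording.
#' @return A [perfusion_recording()].
#' @export
generate_bilateral_perfusion <- function(cfg, subject_id = "synthetic",
                                         phase = c("pre", "post")) {
  stopifnot(inherits(cfg, "synth_config"))
  phase <- match.arg(phase)
  fs <- cfg$fs_perfusion
  n <- round(cfg$duration_s * fs)
  if (n < 4L) stop_parameter("duration too short for the sampling rate")
  withr::with_seed(cfg$seed, {
    t <- (seq_len(n) - 1) / fs
    dt <- 1 / fs
    amp   <- exp(0.2 * ou_path(n, dt, tau = 15))
    drift <- 0.3 * ou_path(n, dt, tau = 20)
    shared <- amp * sin(2 * pi * cfg$pf_target * t + drift)
    side <- function() {
      noise <- bandlimited_noise(n, fs)
      myo  <- 0.5 * exp(0.2 * ou_path(n, dt, tau = 30)) *
        sin(2 * pi * 0.1 * t + runif(1, 0, 2 * pi))
      resp <- 0.3 * exp(0.2 * ou_path(n, dt, tau = 30)) *
        sin(2 * pi * 0.3 * t + runif(1, 0, 2 * pi))
      noise + myo + resp
    }
    sf <- cfg$shared_fraction
    left  <- 50 + 10 * (sf * shared + (1 - sf) * side())
    right <- 50 +  9 * (sf * shared + (1 - sf) * side())
    perfusion_recording(t, left, right, fs,
                        subject_id = subject_id, phase = phase)
  })
}

#' Generate an RR-interval series
#'
#' RR intervals follow
#' `RR_i = mean_rr_ms + rsa_amplitude_ms * sin(2 pi 0.25 t_i)
#'  + lf_amplitude_ms * sin(2 pi 0.1 t_i + phi) + N(0, jitter_ms)`,
#' with `t_i` the cumulative onset time, so respiratory sinus arrhythmia
#' depth maps directly onto RMSSD/SD1 and the slow modulation onto SD2.
#'
#' @param cfg A [synth_config()].
#' @param subject_id,phase Labels stored on the series.
#' @return An [rr_series()] spanning approximately `duration_s` seconds.
#' @export
generate_rr_series <- function(cfg, subject_id = "synthetic",
                               phase = c("pre", "post")) {
  stopifnot(inherits(cfg, "synth_config"))
  phase <- match.arg(phase)
  withr::with_seed(cfg$seed, {
    n_guess <- ceiling(cfg$duration_s * 1000 / cfg$mean_rr_ms * 1.5) + 16L
    rr <- numeric(n_guess)
    tt <- numeric(n_guess)
    phi <- runif(1, 0, 2 * pi)
    t_cur <- 0
    i <- 0L
    while (t_cur < cfg$duration_s && i < n_guess) {
      i <- i + 1L
      val <- cfg$mean_rr_ms +
        cfg$rsa_amplitude_ms * sin(2 * pi * 0.25 * t_cur) +
        cfg$lf_amplitude_ms * sin(2 * pi * 0.10 * t_cur + phi) +
        rnorm(1, 0, cfg$jitter_ms)
      if (val <= 0)
        stop_parameter("parameters produce a non-positive RR interval")
      rr[i] <- val
      tt[i] <- t_cur
      t_cur <- t_cur + val / 1000
    }
    rr_series(rr[seq_len(i)], t = tt[seq_len(i)],
              subject_id = subject_id, phase = phase)
  })
}

#' Generate a multichannel EGG recording
#'
#' Each channel contains a gastric slow wave (sinusoid at
#' `egg_df_cpm / 60` Hz with a gentle amplitude modulation) at a
#' channel-specific amplitude plus 1/f-like noise.  One randomly chosen
#' channel is given a clearly largest slow-wave amplitude so the
#' max-peak-channel rule of [dominant_frequency()] has a well-defined
#' target.
#'
#' @param cfg A [synth_config()].
#' @param subject_id,phase Labels stored on the recording.
#' @return An [egg_recording()]; the designated maximum-amplitude channel is
#'   stored in attribute `"max_channel"`.
#' @export
generate_egg <- function(cfg, subject_id = "synthetic",
                         phase = c("pre", "post")) {
  stopifnot(inherits(cfg, "synth_config"))
  phase <- match.arg(phase)
  fs <- cfg$fs_egg
  n <- round(cfg$duration_s * fs)
  nc <- cfg$n_channels_egg
  withr::with_seed(cfg$seed, {
    t <- (seq_len(n) - 1) / fs
    f0 <- cfg$egg_df_cpm / 60
    amps <- runif(nc, 0.4, 0.9)
    max_ch <- sample.int(nc, 1L)
    amps[max_ch] <- 1.5
    ch <- matrix(0, n, nc)
    for (j in seq_len(nc)) {
      moddepth <- 0.2 * sin(2 * pi * t / (cfg$duration_s * 2) +
                              runif(1, 0, 2 * pi))
      wave <- amps[j] * (1 + moddepth) * sin(2 * pi * f0 * t +
                                               runif(1, 0, 2 * pi))
      ch[, j] <- wave + cfg$egg_noise_amp * one_over_f_noise(n, fs)
    }
    rec <- egg_recording(ch, fs, subject_id = subject_id, phase = phase)
    attr(rec, "max_channel") <- max_ch
    rec
  })
}

# 1/f amplitude-shaped Gaussian noise via frequency-domain synthesis.
one_over_f_noise <- function(n, fs) {
  x <- rnorm(n)
  X <- fft(x)
  f <- c(1, seq_len(n - 1)) * fs / n  # avoid division by zero at DC
  f <- pmin(f, fs - f + fs / n)       # mirror for the negative frequencies
  X <- X / sqrt(f)
  y <- Re(fft(X, inverse = TRUE)) / n
  y / max(sd(y), .Machine$double.eps)
}

#' Specification of a synthetic PF/index cohort
#'
#' Parameters of the linear coupling between the blood-flow coherence peak
#' frequency (PF) and the sympathetic/parasympathetic indices.  The default
#' slopes, intercepts and coefficients of determination are the fitted
#' values of the study models `SNSi = 6.48 PF - 7.23` (R^2 = 0.779) and
#' `PNSi = -5.27 PF + 5.96` (R^2 = 0.686); the default group structure is
#' three temperature-stimulus groups of 20 subjects.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param groups Group labels.
#' @param slope_snsi,intercept_snsi Generating SNSi model coefficients.
#' @param slope_pnsi,intercept_pnsi Generating PNSi model coefficients.
#' @param r2_snsi,r2_pnsi Target population R^2 in (0, 1]; noise SDs are
#'   calibrated as `sigma^2 = slope^2 Var(PF) (1 - R2) / R2`.
#' @param pf_bounds Bounds of the uniform PF distribution (within
#'   \[1.0, 1.5\]).
#' @param group_pf_shift Additive PF shift (Hz) per group, recycled/named to
#'   `groups`; mimics the post-stimulus separation between temperature
#'   groups.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 20L, groups = c("4C", "10C", "30C"),
                        slope_snsi = 6.48, intercept_snsi = -7.23,
                        slope_pnsi = -5.27, intercept_pnsi = 5.96,
                        r2_snsi = 0.779, r2_pnsi = 0.686,
                        pf_bounds = c(1.0, 1.5),
                        group_pf_shift = c(0.06, 0.03, 0)) {
  check_number(n_per_group, "n_per_group", lower = 2)
  groups <- as.character(groups)
  if (anyDuplicated(groups)) stop_parameter("group labels must be unique")
  check_number(r2_snsi, "r2_snsi", 0, 1, strict_lower = TRUE)
  check_number(r2_pnsi, "r2_pnsi", 0, 1, strict_lower = TRUE)
  pf_bounds <- check_band(pf_bounds, "pf_bounds")
  if (pf_bounds[1] < 1.0 || pf_bounds[2] > 1.5 ||
      pf_bounds[1] >= pf_bounds[2])
    stop_parameter("pf_bounds must be a non-degenerate interval within [1.0, 1.5]")
  if (length(group_pf_shift) == 1L)
    group_pf_shift <- rep(group_pf_shift, length(groups))
  if (length(group_pf_shift) != length(groups))
    stop_parameter("group_pf_shift must match groups in length")
  names(group_pf_shift) <- groups
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 slope_snsi = slope_snsi, intercept_snsi = intercept_snsi,
                 slope_pnsi = slope_pnsi, intercept_pnsi = intercept_pnsi,
                 r2_snsi = r2_snsi, r2_pnsi = r2_pnsi,
                 pf_bounds = pf_bounds, group_pf_shift = group_pf_shift),
            class = "cohort_spec")
}

#' Generate a synthetic cohort table
#'
#' Draws per-subject PF values uniformly on `pf_bounds`, adds the group PF
#' shift (clipped to \[1.0, 1.5\]), and generates SNSi/PNSi from the linear
#' models of the [cohort_spec()] plus Gaussian noise whose variance
#' `slope^2 Var(PF) (1 - R2) / R2` makes the population coefficient of
#' determination equal to the requested R^2 (`Var(PF)` is the variance of
#' the uniform law on `pf_bounds`).
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param phase Phase label written to every row.
#' @return A `data.frame` with columns `subject_id`, `group`, `phase`,
#'   `pf`, `snsi`, `pnsi`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(), seed = 1)
#' head(cohort)
#' @export
generate_cohort <- function(spec, seed, phase = "post") {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- as.integer(check_number(seed, "seed"))
  var_pf <- diff(spec$pf_bounds)^2 / 12
  sd_snsi <- abs(spec$slope_snsi) *
    sqrt(var_pf * (1 - spec$r2_snsi) / spec$r2_snsi)
  sd_pnsi <- abs(spec$slope_pnsi) *
    sqrt(var_pf * (1 - spec$r2_pnsi) / spec$r2_pnsi)
  n_tot <- spec$n_per_group * length(spec$groups)
  withr::with_seed(seed, {
    group <- rep(spec$groups, each = spec$n_per_group)
    pf <- runif(n_tot, spec$pf_bounds[1], spec$pf_bounds[2]) +
      spec$group_pf_shift[group]
    pf <- pmin(pmax(pf, 1.0), 1.5)
    snsi <- spec$slope_snsi * pf + spec$intercept_snsi +
      rnorm(n_tot, 0, sd_snsi)
    pnsi <- spec$slope_pnsi * pf + spec$intercept_pnsi +
      rnorm(n_tot, 0, sd_pnsi)
    data.frame(subject_id = sprintf("s%03d", seq_len(n_tot)),
               group = group, phase = phase, pf = as.numeric(pf),
               snsi = snsi, pnsi = pnsi, stringsAsFactors = FALSE)
  })
}
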