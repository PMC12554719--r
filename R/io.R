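# Readers and writers for the plain-text formats flowing through the
# pipeline.  All readers validate the domain invariants at load time and
# reject rather than silently coerce bad data.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

has_header <- function(path, sep) {
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  any(is.na(suppressWarnings(as.numeric(first))))
}

read_delim_file <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  sep <- detect_sep(path)
  read.table(path, sep = sep, header = has_header(path, sep),
             stringsAsFactors = FALSE)
}

#' Read a bilateral perfusion recording
#'
#' Parses a tab- or comma-separated file with columns (time s, left PU,
#' right PU), with or without a header line.  The sampling rate is inferred
#' from the median time step; a warning is recorded if it departs from the
#' nominal hardware rate or if the time steps are irregular (jitter above
#' 5% of the median step).
#'
#' @param path Path to the file.
#' @param subject_id,phase Labels attached to the recording.
#' @param nominal_fs Expected sampling rate in Hz (default 64).
#' @return A [perfusion_recording()].
#' @export
read_perfusion <- function(path, subject_id = "s1", phase = "pre",
                           nominal_fs = 64) {
  d <- read_delim_file(path)
  if (ncol(d) < 3L)
    stop_format(sprintf("%s: expected 3 columns (time, left, right), found %d",
                        basename(path), ncol(d)))
  d <- d[, 1:3]
  names(d) <- c("time", "left", "right")
  if (any(diff(d$time) <= 0))
    stop_data(sprintf("%s: time column is not strictly increasing",
                      basename(path)))
  dt <- diff(d$time)
  fs <- 1 / median(dt)
  if (abs(fs - nominal_fs) / nominal_fs > 0.02)
    warning(sprintf("%s: inferred rate %.2f Hz differs from nominal %g Hz",
                    basename(path), fs, nominal_fs))
  if (max(abs(dt - median(dt))) > 0.05 * median(dt))
    warning(sprintf("%s: irregular time steps (jitter > 5%%)",
                    basename(path)))
  perfusion_recording(d$time, d$left, d$right, fs,
                      subject_id = subject_id, phase = phase)
}

#' Write a perfusion recording
#'
#' Emits the same comma-separated dialect [read_perfusion()] consumes,
#' floats at 10 significant digits.
#'
#' @param rec A [perfusion_recording()].
#' @param path Output path.
#' @export
write_perfusion <- function(rec, path) {
  stopifnot(inherits(rec, "perfusion_recording"))
  d <- data.frame(time_s = signif(rec$time, 10),
                  left_pu = signif(rec$left, 10),
                  right_pu = signif(rec$right, 10))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an RR-interval series
#'
#' Accepts either a plain text file with one RR value (ms) per line, or a
#' two-column CSV (t_s, rr_ms).
#'
#' @param path Path to the file.
#' @param subject_id,phase Labels attached to the series.
#' @return An [rr_series()].
#' @export
read_rr <- function(path, subject_id = "s1", phase = "pre") {
  d <- read_delim_file(path)
  if (ncol(d) == 1L) {
    rr <- d[[1]]
    t <- NULL
  } else {
    t <- d[[1]]
    rr <- d[[2]]
  }
  if (any(!is.finite(rr)) || any(rr <= 0))
    stop_format(sprintf("%s: non-positive RR at line %d",
                        basename(path),
                        which(!is.finite(rr) | rr <= 0)[1]))
  rr_series(rr, t = t, subject_id = subject_id, phase = phase)
}

#' Write an RR series (one ms value per line)
#' @param rr An [rr_series()].
#' @param path Output path.
#' @export
write_rr <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  writeLines(format(signif(rr$rr, 10), trim = TRUE, scientific = FALSE),
             path)
  invisible(path)
}

#' Read a multichannel EGG recording
#'
#' Expects a delimited file whose first column is time (s) and remaining
#' columns are EGG channels (microvolts); the sampling rate is inferred
#' from the median time step.
#'
#' @param path Path to the file.
#' @param subject_id,phase Labels attached to the recording.
#' @return An [egg_recording()].
#' @export
read_egg <- function(path, subject_id = "s1", phase = "pre") {
  d <- read_delim_file(path)
  if (ncol(d) < 2L)
    stop_format(sprintf("%s: expected time plus at least one channel",
                        basename(path)))
  t <- d[[1]]
  if (any(diff(t) <= 0))
    stop_data(sprintf("%s: time column is not strictly increasing",
                      basename(path)))
  fs <- 1 / median(diff(t))
  egg_recording(as.matrix(d[, -1, drop = FALSE]), fs,
                channel_labels = names(d)[-1],
                subject_id = subject_id, phase = phase)
}

#' Write an EGG recording
#' @param rec An [egg_recording()].
#' @param path Output path.
#' @export
write_egg <- function(rec, path) {
  stopifnot(inherits(rec, "egg_recording"))
  n <- nrow(rec$channels)
  d <- data.frame(time_s = signif((seq_len(n) - 1) / rec$fs, 10))
  d <- cbind(d, as.data.frame(signif(rec$channels, 10)))
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort table
#'
#' Expects columns `subject_id`, `group`, `phase`, `pf`, `pnsi`, `snsi`
#' (and optionally `df`).  Duplicate (subject, phase) rows are rejected.
#'
#' @param path Path to a CSV/TSV file.
#' @return A validated cohort `data.frame`.
#' @export
read_cohort <- function(path) {
  d <- read_delim_file(path)
  need <- c("subject_id", "group", "phase", "pf", "pnsi", "snsi")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop_format(sprintf("%s: missing column(s): %s", basename(path),
                        paste(missing_cols, collapse = ", ")))
  key <- paste(d$subject_id, d$phase)
  if (anyDuplicated(key))
    stop_data(sprintf("%s: duplicate (subject, phase): %s", basename(path),
                      key[duplicated(key)][1]))
  d
}

#' Write a cohort table
#' @param cohort A cohort `data.frame`.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  num <- vapply(cohort, is.numeric, logical(1))
  cohort[num] <- lapply(cohort[num], signif, digits = 10)
  write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
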