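# End-to-end orchestration: simulate a full study at the signal level,
# run the perfusion/HRV/EGG stages over a directory of recordings, and
# assemble the correlation/regression reports.

#' Pipeline configuration
#'
#' Bundles every analysis parameter of [run_pipeline()].
#'
#' @param pf_band PF band in Hz (default `c(1.0, 1.5)`).
#' @param egg_band EGG dominant-frequency band in Hz
#'   (default `c(0.033, 0.066)`).
#' @param segment_len,overlap_fraction,window_name Coherence estimator
#'   settings, see [compute_coherence()].
#' @param lambda Smoothness-priors regularization (default 500).
#' @param artifact_level RR artifact correction level (default `"medium"`).
#' @param norms An [hrv_norms()] object, or a path to a YAML norms file.
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed recorded in the manifest.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(pf_band = c(1.0, 1.5),
                            egg_band = c(0.033, 0.066),
                            segment_len = 4096, overlap_fraction = 0.5,
                            window_name = "hann", lambda = 500,
                            artifact_level = "medium", norms = hrv_norms(),
                            alpha = 0.05, seed = 1L) {
  if (is.character(norms)) norms <- read_norms(norms)
  stopifnot(inherits(norms, "hrv_norms"))
  structure(list(
    pf_band = check_band(pf_band, "pf_band"),
    egg_band = check_band(egg_band, "egg_band"),
    segment_len = segment_len, overlap_fraction = overlap_fraction,
    window_name = window_name, lambda = lambda,
    artifact_level = artifact_level, norms = norms,
    alpha = check_number(alpha, "alpha", 0, 1, strict_lower = TRUE,
                         strict_upper = TRUE),
    seed = as.integer(check_number(seed, "seed"))),
    class = "pipeline_config")
}

#' Simulate a full study at the signal level
#'
#' Generates, for every synthetic subject, a bilateral perfusion recording
#' whose shared-oscillator frequency is the subject's true PF, and an RR
#' series whose mean RR and respiratory-sinus-arrhythmia depth are coupled
#' to that PF (shorter RR / shallower RSA at higher PF).  Running the full
#' pipeline on the output therefore reproduces the qualitative study
#' structure: SNSi increases and PNSi decreases with PF.  Post-stimulus
#' recordings add the group PF shift.
#'
#' @param n_per_group Subjects per group.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @param groups Group labels.
#' @param group_pf_shift Post-stimulus PF shift (Hz) per group.
#' @param phases Phases to simulate (`"pre"`, `"post"` or both).
#' @param duration_s Recording duration per phase (seconds).
#' @param shared_fraction Shared-oscillator weight of the perfusion model.
#' @param include_egg Also generate EGG recordings (slower; default FALSE).
#' @param fs_egg EGG sampling rate used when `include_egg` is TRUE.
#' @param dir Optional directory; when given, recordings are written as
#'   `perfusion_<subject>_<phase>.csv`, `rr_<subject>_<phase>.csv`,
#'   `egg_<subject>_<phase>.csv` plus `groups.csv`, the on-disk contract of
#'   [run_pipeline()].
#' @return List with `recordings` (perfusion), `rr`, `egg` (or NULL) and
#'   `truth` (data.frame of per-subject generating parameters).
#' @export
simulate_study <- function(n_per_group = 20L, seed = 1L,
                           groups = c("4C", "10C", "30C"),
                           group_pf_shift = c(0.06, 0.03, 0),
                           phases = c("pre", "post"),
                           duration_s = 300, shared_fraction = 0.7,
                           include_egg = FALSE, fs_egg = 10,
                           dir = NULL) {
  seed <- as.integer(check_number(seed, "seed"))
  phases <- match.arg(phases, c("pre", "post"), several.ok = TRUE)
  names(group_pf_shift) <- groups
  n_tot <- n_per_group * length(groups)
  plan <- withr::with_seed(seed, {
    u <- runif(n_tot)
    data.frame(subject_id = sprintf("s%03d", seq_len(n_tot)),
               group = rep(groups, each = n_per_group),
               u = u,
               sub_seed = sample.int(.Machine$integer.max - 1L, 2L * n_tot)[
                 seq_len(n_tot)],
               rr_seed = sample.int(.Machine$integer.max - 1L, 2L * n_tot)[
                 n_tot + seq_len(n_tot)],
               stringsAsFactors = FALSE)
  })
  recs <- list(); rrs <- list(); eggs <- if (include_egg) list() else NULL
  truth <- list()
  for (ph in phases) {
    for (i in seq_len(n_tot)) {
      shift <- if (ph == "post") group_pf_shift[[plan$group[i]]] else 0
      pf <- min(max(1.05 + 0.38 * plan$u[i] + shift, 1.02), 1.48)
      v <- (pf - 1.0) / 0.5  # coupling variable in (0, 1)
      cfg <- synth_config(
        seed = (plan$sub_seed[i] + as.integer(ph == "post")) %%
          .Machine$integer.max,
        duration_s = duration_s, pf_target = pf,
        shared_fraction = shared_fraction,
        mean_rr_ms = 1050 - 350 * v, rsa_amplitude_ms = 68 - 48 * v,
        lf_amplitude_ms = 25, jitter_ms = 5,
        egg_df_cpm = 2.5 + plan$u[i], fs_egg = fs_egg)
      key <- paste0(plan$subject_id[i], "_", ph)
      recs[[key]] <- generate_bilateral_perfusion(
        cfg, subject_id = plan$subject_id[i], phase = ph)
      rr_cfg <- cfg
      rr_cfg$seed <- (plan$rr_seed[i] + as.integer(ph == "post")) %%
        .Machine$integer.max
      rrs[[key]] <- generate_rr_series(rr_cfg,
                                       subject_id = plan$subject_id[i],
                                       phase = ph)
      if (include_egg)
        eggs[[key]] <- generate_egg(cfg, subject_id = plan$subject_id[i],
                                    phase = ph)
      truth[[key]] <- data.frame(
        subject_id = plan$subject_id[i], group = plan$group[i], phase = ph,
        pf_true = pf, mean_rr_ms = cfg$mean_rr_ms,
        rsa_amplitude_ms = cfg$rsa_amplitude_ms,
        egg_df_cpm = cfg$egg_df_cpm, stringsAsFactors = FALSE)
    }
  }
  out <- list(recordings = recs, rr = rrs, egg = eggs,
              truth = do.call(rbind, truth))
  rownames(out$truth) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (key in names(recs))
      write_perfusion(recs[[key]], file.path(dir,
                                             paste0("perfusion_", key, ".csv")))
    for (key in names(rrs))
      write_rr(rrs[[key]], file.path(dir, paste0("rr_", key, ".csv")))
    if (include_egg)
      for (key in names(eggs))
        write_egg(eggs[[key]], file.path(dir, paste0("egg_", key, ".csv")))
    write.csv(unique(out$truth[, c("subject_id", "group")]),
              file.path(dir, "groups.csv"), row.names = FALSE, quote = FALSE)
  }
  out
}

parse_stage_files <- function(input_dir, prefix) {
  files <- list.files(input_dir,
                      pattern = paste0("^", prefix, "_.+_(pre|post)\\.csv$"))
  if (length(files) == 0L) return(NULL)
  m <- regmatches(files, regexec(paste0("^", prefix, "_(.+)_(pre|post)\\.csv$"),
                                 files))
  data.frame(file = file.path(input_dir, files),
             subject_id = vapply(m, `[`, character(1), 2L),
             phase = vapply(m, `[`, character(1), 3L),
             stringsAsFactors = FALSE)
}

#' Run the end-to-end analysis pipeline over a directory
#'
#' Consumes a directory of `perfusion_<subject>_<phase>.csv`,
#' `rr_<subject>_<phase>.csv` and optional `egg_<subject>_<phase>.csv`
#' files (plus an optional `groups.csv` with columns subject_id, group),
#' runs coherence/PF extraction, the HRV pipeline and EGG DF estimation,
#' assembles the cohort table, and computes Spearman PF--index correlations
#' (per phase and pooled, FDR-corrected over the whole correlation family)
#' and the pooled PF regressions for both indices.  Per-subject failures
#' are isolated and reported; the pipeline fails only if no subject
#' succeeds.
#'
#' @param input_dir Input directory.
#' @param out_dir Optional output directory; when given, the PF/HRV/DF and
#'   cohort tables are written as CSV, the statistical results as
#'   `results.json`, and a reproducibility manifest (configuration, seed,
#'   package version, input file hashes) as `manifest.json`.
#' @param config A [pipeline_config()].
#' @return List with `pf_table`, `hrv_table`, `df_table`, `cohort`,
#'   `correlations` (data.frame with rho/p/p_fdr per phase and index),
#'   `regressions` (list of `pf_regression`), `failures`, `manifest`.
#' @export
run_pipeline <- function(input_dir, out_dir = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(input_dir))
    stop_input(sprintf("input directory not found: %s", input_dir))
  perf_files <- parse_stage_files(input_dir, "perfusion")
  rr_files <- parse_stage_files(input_dir, "rr")
  egg_files <- parse_stage_files(input_dir, "egg")
  if (is.null(perf_files) && is.null(rr_files))
    stop_input(sprintf("no subject files found in %s", input_dir))

  failures <- list()
  note_failure <- function(stage, subject, phase, e) {
    failures[[length(failures) + 1L]] <<- data.frame(
      stage = stage, subject_id = subject, phase = phase,
      error = conditionMessage(e), stringsAsFactors = FALSE)
  }

  # perfusion -> PF
  pf_table <- NULL
  if (!is.null(perf_files)) {
    recs <- list()
    for (k in seq_len(nrow(perf_files))) {
      r <- tryCatch(read_perfusion(perf_files$file[k],
                                   subject_id = perf_files$subject_id[k],
                                   phase = perf_files$phase[k]),
                    error = function(e) e)
      if (inherits(r, "error"))
        note_failure("read_perfusion", perf_files$subject_id[k],
                     perf_files$phase[k], r)
      else recs[[length(recs) + 1L]] <- r
    }
    if (length(recs)) {
      pf_table <- suppressWarnings(pf_for_cohort(
        recs, band = config$pf_band, segment_len = config$segment_len,
        overlap_fraction = config$overlap_fraction,
        window_name = config$window_name))
      pfail <- attr(pf_table, "failures")
      if (NROW(pfail))
        for (k in seq_len(nrow(pfail)))
          note_failure("coherence", pfail$subject_id[k], pfail$phase[k],
                       simpleError(pfail$error[k]))
    }
  }

  # RR -> HRV metrics
  hrv_table <- NULL
  if (!is.null(rr_files)) {
    rows <- list()
    for (k in seq_len(nrow(rr_files))) {
      res <- tryCatch({
        rr <- read_rr(rr_files$file[k], subject_id = rr_files$subject_id[k],
                      phase = rr_files$phase[k])
        m <- suppressWarnings(hrv_pipeline(
          rr, norms = config$norms, lambda = config$lambda,
          artifact_level = config$artifact_level))
        data.frame(subject_id = m$subject_id, phase = m$phase,
                   mean_rr = m$mean_rr, mean_hr = m$mean_hr,
                   rmssd = m$rmssd, sd1 = m$sd1, sd2 = m$sd2,
                   baevsky_si = m$baevsky_si, pnsi = m$pnsi, snsi = m$snsi,
                   stringsAsFactors = FALSE)
      }, error = function(e) e)
      if (inherits(res, "error"))
        note_failure("hrv", rr_files$subject_id[k], rr_files$phase[k], res)
      else rows[[length(rows) + 1L]] <- res
    }
    if (length(rows)) hrv_table <- do.call(rbind, rows)
  }

  # EGG -> DF
  df_table <- NULL
  if (!is.null(egg_files)) {
    rows <- list()
    for (k in seq_len(nrow(egg_files))) {
      res <- tryCatch({
        rec <- read_egg(egg_files$file[k],
                        subject_id = egg_files$subject_id[k],
                        phase = egg_files$phase[k])
        spec <- egg_power_spectrum(rec)
        df <- dominant_frequency(spec, band = config$egg_band)
        data.frame(subject_id = rec$subject_id, phase = rec$phase,
                   df = df$subject_df, channel = df$subject_channel,
                   stringsAsFactors = FALSE)
      }, error = function(e) e)
      if (inherits(res, "error"))
        note_failure("egg", egg_files$subject_id[k], egg_files$phase[k], res)
      else rows[[length(rows) + 1L]] <- res
    }
    if (length(rows)) df_table <- do.call(rbind, rows)
  }

  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(stage = character(), subject_id = character(),
               phase = character(), error = character(),
               stringsAsFactors = FALSE)
  if (is.null(pf_table) && is.null(hrv_table))
    stop_quality("no subject produced any usable result")

  # assemble the cohort table
  groups_path <- file.path(input_dir, "groups.csv")
  group_map <- if (file.exists(groups_path))
    read.table(groups_path, sep = ",", header = TRUE,
               stringsAsFactors = FALSE) else NULL
  cohort <- NULL
  if (!is.null(pf_table) && !is.null(hrv_table)) {
    cohort <- merge(pf_table,
                    hrv_table[, c("subject_id", "phase", "pnsi", "snsi")],
                    by = c("subject_id", "phase"))
    if (!is.null(df_table))
      cohort <- merge(cohort, df_table[, c("subject_id", "phase", "df")],
                      by = c("subject_id", "phase"), all.x = TRUE)
    cohort$group <- if (!is.null(group_map))
      group_map$group[match(cohort$subject_id, group_map$subject_id)] else
        "all"
    cohort <- cohort[order(cohort$subject_id, cohort$phase), ]
    rownames(cohort) <- NULL
  }

  # correlations (per phase and pooled) + pooled regressions
  correlations <- NULL
  regressions <- NULL
  if (!is.null(cohort) && nrow(cohort) >= 3L) {
    scopes <- c(intersect(c("pre", "post"), unique(cohort$phase)), "pooled")
    rows <- list()
    for (sc in scopes) {
      d <- if (sc == "pooled") cohort else cohort[cohort$phase == sc, ]
      for (idx in c("snsi", "pnsi")) {
        if (nrow(d) < 3L) next
        ct <- tryCatch(spearman_cor(d$pf, d[[idx]]), error = function(e) NULL)
        if (!is.null(ct))
          rows[[length(rows) + 1L]] <- data.frame(
            scope = sc, index = idx, rho = ct$rho, p = ct$p, n = ct$n,
            stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) {
      correlations <- do.call(rbind, rows)
      correlations$p_fdr <- fdr_adjust(correlations$p)
    }
    regressions <- list(
      snsi = tryCatch(fit_pf_regression(cohort, "snsi"),
                      error = function(e) NULL),
      pnsi = tryCatch(fit_pf_regression(cohort, "pnsi"),
                      error = function(e) NULL))
  }

  manifest <- list(
    package = "ansflow",
    version = as.character(utils::packageVersion("ansflow")),
    seed = config$seed,
    config = config[setdiff(names(config), "norms")],
    norms = unclass(config$norms),
    inputs = as.list(tools::md5sum(sort(list.files(input_dir,
                                                   full.names = TRUE)))))

  bundle <- list(pf_table = pf_table, hrv_table = hrv_table,
                 df_table = df_table, cohort = cohort,
                 correlations = correlations, regressions = regressions,
                 failures = failures, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(pf_table)) write_cohort(pf_table,
                                         file.path(out_dir, "pf_table.csv"))
    if (!is.null(hrv_table)) write_cohort(hrv_table,
                                          file.path(out_dir, "hrv_table.csv"))
    if (!is.null(df_table)) write_cohort(df_table,
                                         file.path(out_dir, "df_table.csv"))
    if (!is.null(cohort)) write_cohort(cohort,
                                       file.path(out_dir, "cohort.csv"))
    results <- list(
      correlations = correlations,
      regressions = lapply(regressions, function(f) if (is.null(f)) NULL else
        f[c("slope", "intercept", "r2", "p_value", "residual_sd", "n")]),
      failures = failures)
    jsonlite::write_json(results, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  bundle
}
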