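#' Process one recording into trial-level band power
#'
#' Runs the signal chain for a single recording: channel selection by
#' trial-period variability, three-channel demeaning, conditioning to
#' 1000 Hz, Morlet decomposition, theta / low-beta / broadband power,
#' response-locked epoching with the configured baseline policy, and the
#' per-trial inclusion test (broadband by default).
#'
#' @param rec An [recording()].
#' @param trials The subject's trial table (rows at `rec$subregion` are
#'   used).
#' @param preproc An [preproc_config()].
#' @param tf An [tf_config()].
#' @return A list with `trial_band` (per trial x band: QC flag, raw-power
#'   time-bin means, analysis-window mean, baseline mean and sum of squared
#'   deviations) and `dropped` (per-trial exclusion reasons).
#' @export
process_recording <- function(rec, trials, preproc = preproc_config(),
                              tf = tf_config()) {
  trials_depth <- trials[trials$depth == rec$subregion, , drop = FALSE]
  sel <- select_channel(rec, trials_depth)
  dem <- demean_channels(rec)
  x <- condition_signal(dem$channels[, sel], rec$fs_raw, preproc)
  tfr <- morlet_power(x, preproc$fs_target, tf)
  series <- list(
    theta = band_power(tfr, tf$theta_band),
    beta = band_power(tfr, tf$beta_band),
    broadband = colMeans(tfr$power)
  )
  rm(tfr)
  ep <- lapply(series, extract_epochs, trials = trials_depth, config = tf,
               fs = preproc$fs_target)

  epochs <- ep$theta$epochs
  n_ep <- nrow(epochs)
  out <- vector("list", 2L * max(n_ep, 0L))
  if (n_ep > 0) {
    for (i in seq_len(n_ep)) {
      qc_src <- if (tf$qc_band == "broadband") "broadband" else NULL
      qc_broad <- qc_trial(ep$broadband$epochs$epoch[[i]],
                           ep$broadband$epochs$baseline[[i]], tf$qc_alpha)
      for (band in c("theta", "beta")) {
        e <- ep[[band]]$epochs$epoch[[i]]
        b <- ep[[band]]$epochs$baseline[[i]]
        qc <- if (tf$qc_band == "broadband") qc_broad else {
          qc_trial(e, b, tf$qc_alpha)
        }
        bins <- bin_power(e, tf$n_bins)
        out[[2L * (i - 1L) + match(band, c("theta", "beta"))]] <-
          tibble::tibble(
            subject_id = rec$subject_id, subregion = rec$subregion,
            hemisphere = rec$hemisphere,
            trial_id = epochs$trial_id[i],
            correspondence = epochs$correspondence[i],
            hemisphere_rel = relabel_hemisphere(rec$hemisphere,
                                                epochs$response_side[i]),
            band = band, included = qc$included, qc_p = qc$p,
            qc_reason = qc$reason,
            !!!setNames(as.list(bins), paste0("bin", seq_along(bins))),
            analysis_mean = mean(e), base_mean = mean(b),
            base_ss = sum((b - mean(b))^2), base_n = length(b)
          )
      }
    }
  }
  dropped <- ep$theta$dropped
  if (nrow(dropped) > 0) {
    dropped <- dplyr::mutate(dropped, subject_id = rec$subject_id,
                             subregion = rec$subregion,
                             hemisphere = rec$hemisphere, .before = 1)
  }
  list(trial_band = dplyr::bind_rows(out), dropped = dropped)
}

#' Assemble power cells for a whole cohort
#'
#' Runs [process_recording()] over every recording, pools each subject's
#' baselines within subregion x band for z-scoring, normalizes each trial by
#' its own baseline mean (ratio scale), averages the four time-bin means
#' across a subject's included trials within each subregion x relative
#' hemisphere x correspondence cell, and log-transforms the cell means.
#'
#' @param cohort An `stn_cohort` from [simulate_cohort()] (with signals) or
#'   [read_cohort()].
#' @param preproc An [preproc_config()].
#' @param tf An [tf_config()].
#' @return A list with `powercells` (per band x subject x subregion x
#'   relative hemisphere x correspondence x time bin: `n_trials`,
#'   `mean_ratio`, `mean_z`, `log_power`), `qc_log` (every excluded trial
#'   with a reason code), `qc_rate` (exclusion percentages), and
#'   `baseline` (per subject x subregion x band mean baseline power in dB).
#' @export
compute_powercells <- function(cohort, preproc = preproc_config(),
                               tf = tf_config()) {
  stopifnot(inherits(cohort, "stn_cohort"))
  if (is.null(cohort$recordings)) {
    stn_error("cohort has no signal recordings (simulated with signals = FALSE).",
              "stnlfp_config_error")
  }
  res <- purrr::map(seq_len(nrow(cohort$recordings)), function(i) {
    row <- cohort$recordings[i, ]
    trials <- cohort$trials[cohort$trials$subject_id == row$subject_id, ,
                            drop = FALSE]
    process_recording(row$recording[[1]], trials, preproc, tf)
  })
  trial_band <- dplyr::bind_rows(purrr::map(res, "trial_band"))
  dropped <- dplyr::bind_rows(purrr::map(res, "dropped"))

  pooled <- trial_band |>
    dplyr::group_by(.data$subject_id, .data$subregion, .data$band) |>
    dplyr::summarise(
      pool_mean = sum(.data$base_mean * .data$base_n) / sum(.data$base_n),
      pool_sd = sqrt((sum(.data$base_ss) +
                        sum(.data$base_n * (.data$base_mean - .data$pool_mean)^2)) /
                       (sum(.data$base_n) - 1)),
      .groups = "drop"
    )

  bins <- grep("^bin[0-9]+$", names(trial_band), value = TRUE)
  long <- trial_band |>
    dplyr::left_join(pooled, by = c("subject_id", "subregion", "band")) |>
    tidyr::pivot_longer(dplyr::all_of(bins), names_to = "time_bin",
                        values_to = "raw_power") |>
    dplyr::mutate(
      time_bin = as.integer(sub("^bin", "", .data$time_bin)),
      ratio = .data$raw_power / .data$base_mean,
      z = (.data$raw_power - .data$pool_mean) / .data$pool_sd
    )

  powercells <- long |>
    dplyr::filter(.data$included) |>
    dplyr::group_by(.data$band, .data$subject_id, .data$subregion,
                    .data$hemisphere_rel, .data$correspondence,
                    .data$time_bin) |>
    dplyr::summarise(n_trials = dplyr::n(), mean_ratio = mean(.data$ratio),
                     mean_z = mean(.data$z), .groups = "drop") |>
    dplyr::mutate(log_power = as.numeric(log_transform(.data$mean_ratio)))

  qc_trials <- trial_band |>
    dplyr::distinct(.data$subject_id, .data$subregion, .data$hemisphere,
                    .data$trial_id, .data$correspondence, .data$band,
                    .data$included, .data$qc_p, .data$qc_reason)
  qc_excluded <- qc_trials |>
    dplyr::filter(!.data$included) |>
    dplyr::mutate(reason = dplyr::coalesce(.data$qc_reason,
                                           "baseline_not_different")) |>
    dplyr::select(-"qc_reason")
  qc_log <- dplyr::bind_rows(
    qc_excluded,
    if (nrow(dropped) > 0) dplyr::mutate(dropped, band = NA_character_)
  )
  qc_rate <- qc_trials |>
    dplyr::group_by(.data$correspondence) |>
    dplyr::summarise(n = dplyr::n(),
                     excluded_pct = 100 * mean(!.data$included),
                     .groups = "drop")
  qc_rate <- dplyr::bind_rows(
    qc_rate,
    tibble::tibble(correspondence = "all", n = nrow(qc_trials),
                   excluded_pct = 100 * mean(!qc_trials$included))
  )

  baseline <- trial_band |>
    dplyr::group_by(.data$subject_id, .data$subregion, .data$band) |>
    dplyr::summarise(baseline_db = mean(10 * log10(.data$base_mean)),
                     .groups = "drop")

  list(powercells = powercells, qc_log = qc_log, qc_rate = qc_rate,
       baseline = baseline)
}

#' Write / read a cohort as plain-text containers
#'
#' One trial-table CSV per subject and one recording container per
#' subject x hemisphere x depth, in the formats of [write_trials()] and
#' [write_recording()].
#'
#' @param cohort An `stn_cohort` with signal recordings.
#' @param dir Directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` an
#'   `stn_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "stn_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in unique(cohort$trials$subject_id)) {
    write_trials(cohort$trials[cohort$trials$subject_id == sid, ],
                 file.path(dir, paste0("trials_", sid, ".csv")))
  }
  if (!is.null(cohort$recordings)) {
    for (i in seq_len(nrow(cohort$recordings))) {
      row <- cohort$recordings[i, ]
      write_recording(row$recording[[1]],
                      file.path(dir, paste0("rec_", row$subject_id, "_",
                                            row$hemisphere, "_",
                                            row$subregion)))
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  trial_files <- sort(list.files(dir, pattern = "^trials_.*\\.csv$",
                                 full.names = TRUE))
  if (length(trial_files) == 0) {
    stn_error(sprintf("no trial tables found in '%s'.", dir), "stnlfp_io_error")
  }
  trials <- dplyr::bind_rows(lapply(trial_files, read_trials))
  rec_bases <- sort(unique(sub("\\.(json|csv)$", "",
                               list.files(dir, pattern = "^rec_.*\\.(json|csv)$",
                                          full.names = TRUE))))
  recordings <- NULL
  if (length(rec_bases) > 0) {
    recs <- lapply(rec_bases, read_recording)
    recordings <- tibble::tibble(
      subject_id = purrr::map_chr(recs, "subject_id"),
      hemisphere = purrr::map_chr(recs, "hemisphere"),
      subregion = purrr::map_chr(recs, "subregion"),
      recording = recs
    )
  }
  structure(list(subjects = NULL, trials = trials, recordings = recordings,
                 config = NULL),
            class = "stn_cohort")
}

#' Polynomial rolling hash of a string (provenance fingerprint)
#' @noRd
fnv1a <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or ingest) -> preprocess -> spectral -> behavior
#' -> stats and writes the report bundle: `behavior_summary.csv`,
#' `theta_cells.csv` / `beta_cells.csv` (estimated marginal cell means of
#' log band power with SE), `contrasts.csv`, `correlations.csv`,
#' `powercells.csv`, `qc_log.csv`, and `provenance.json` (configuration,
#' fingerprint, seed). Re-running with the same configuration and seed
#' produces byte-identical CSV output.
#'
#' @param config An [run_config()].
#' @param out_dir Output directory for the report bundle (created if
#'   needed); `NULL` writes nothing.
#' @return An `stn_report` list: `behavior` (an [behavior_summary()]),
#'   `spectral` (the [compute_powercells()] bundle), `fits` (per-band
#'   `stn_lfp_fit`), `contrasts`, `correlations`, and `cohort`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "stn_run_config"))
  cohort <- if (!is.null(config$in_dir)) {
    read_cohort(config$in_dir)
  } else {
    simulate_cohort(config$sim)
  }

  spectral <- compute_powercells(cohort, config$preproc, config$tf)
  behavior <- behavior_summary(cohort$trials)

  fits <- list()
  contrasts <- list()
  for (band in c("theta", "beta")) {
    cells <- dplyr::filter(spectral$powercells, .data$band == !!band)
    fits[[band]] <- fit_mixed(cells, config$model)
    grid <- tidyr::expand_grid(subregion = SUBREGIONS,
                               contrast = c("NC_vs_Cs"))
    per_sub <- purrr::pmap(grid, function(subregion, contrast) {
      dplyr::mutate(
        cell_contrast(fits[[band]],
                      list(subregion = subregion, correspondence = "NC"),
                      list(subregion = subregion, correspondence = "Cs")),
        band = band, scope = paste0(subregion, "_NC_vs_Cs"), .before = 1)
    })
    per_hemi <- purrr::map(HEMI_REL, function(h) {
      dplyr::mutate(
        cell_contrast(fits[[band]],
                      list(hemisphere_rel = h, correspondence = "NC"),
                      list(hemisphere_rel = h, correspondence = "Cs")),
        band = band, scope = paste0(h, "_NC_vs_Cs"), .before = 1)
    })
    contrasts[[band]] <- dplyr::bind_rows(per_sub, per_hemi)
  }
  contrasts <- dplyr::bind_rows(contrasts)

  effects <- behavior$effects
  correlations <- tidyr::expand_grid(
    band = c("theta", "beta"), subregion = SUBREGIONS,
    measure = c("simon_rt_ms", "simon_acc_pct")
  ) |>
    purrr::pmap(function(band, subregion, measure) {
      base <- dplyr::filter(spectral$baseline, .data$band == !!band,
                            .data$subregion == !!subregion)
      beh <- behavior$by_subject |>
        dplyr::filter(.data$depth == !!subregion) |>
        tidyr::pivot_wider(names_from = "correspondence",
                           values_from = c("mean_rt_ms", "accuracy_pct"),
                           id_cols = "subject_id") |>
        dplyr::mutate(
          simon_rt_ms = .data$mean_rt_ms_NC - .data$mean_rt_ms_Cs,
          simon_acc_pct = .data$accuracy_pct_Cs - .data$accuracy_pct_NC
        )
      j <- dplyr::inner_join(base, beh, by = "subject_id")
      ct <- baseline_behavior_correlation(j$baseline_db, j[[measure]])
      dplyr::mutate(ct, band = band, subregion = subregion,
                    measure = measure, .before = 1)
    }) |>
    dplyr::bind_rows()

  report <- structure(
    list(behavior = behavior, spectral = spectral, fits = fits,
         contrasts = contrasts, correlations = correlations,
         cohort = cohort, config = config),
    class = "stn_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, name) readr::write_csv(x, file.path(out_dir, name),
                                            progress = FALSE)
    beh_tbl <- dplyr::left_join(behavior$cells,
                                behavior$effects, by = "depth") |>
      dplyr::left_join(behavior$distribution, by = "depth")
    w(beh_tbl, "behavior_summary.csv")
    for (band in c("theta", "beta")) {
      emm <- as.data.frame(fits[[band]]$emmeans)
      names(emm)[names(emm) == "emmean"] <- "log_power_mean"
      w(emm, paste0(band, "_cells.csv"))
    }
    w(contrasts, "contrasts.csv")
    w(correlations, "correlations.csv")
    w(spectral$powercells, "powercells.csv")
    w(spectral$qc_log, "qc_log.csv")
    cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                                 force = TRUE)
    prov <- list(
      config = jsonlite::fromJSON(cfg_json, simplifyVector = TRUE),
      config_hash = fnv1a(as.character(cfg_json)),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("stnlfp")),
      ladder_steps = purrr::map_chr(fits, "ladder_step")
    )
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.stn_report <- function(x, ...) {
  cat("<stn_report>\n\nQC exclusion:\n")
  print(x$spectral$qc_rate)
  cat("\nFixed-term F tests (theta):\n")
  print(x$fits$theta$anova)
  cat("\nFixed-term F tests (beta):\n")
  print(x$fits$beta$anova)
  cat("\nContrasts:\n")
  print(x$contrasts)
  cat("\nBaseline-power / behavior correlations:\n")
  print(x$correlations)
  invisible(x)
}
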