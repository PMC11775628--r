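RECORDING_SCHEMA <- "stnlfp-recording-1"
TRIALS_SCHEMA <- "stnlfp-trials-1"

#' Write / read a recording container
#'
#' A recording is stored as a pair of plain-text files sharing a base path:
#' `<path>.json` carries the sampling metadata plus a schema-version tag, and
#' `<path>.csv` carries the three channel traces as columns. The round trip
#' is lossless: doubles are written in shortest round-trip representation.
#'
#' @param rec An [recording()] object.
#' @param path Base path (without extension) for the container files.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an `stn_recording`.
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "stn_recording")) {
    stn_error("`rec` must be an stn_recording.", "stnlfp_schema_error")
  }
  meta <- list(
    schema = RECORDING_SCHEMA,
    subject_id = rec$subject_id, hemisphere = rec$hemisphere,
    subregion = rec$subregion, fs_raw = rec$fs_raw, t0 = rec$t0,
    n_samples = nrow(rec$channels)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  # channels are written at full double precision so the round trip is exact
  con <- file(paste0(path, ".csv"), open = "wb")
  on.exit(close(con))
  writeLines("ch1,ch2,ch3", con)
  writeLines(sprintf("%.17g,%.17g,%.17g", rec$channels[, 1],
                     rec$channels[, 2], rec$channels[, 3]), con)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta_path <- paste0(path, ".json")
  csv_path <- paste0(path, ".csv")
  if (!file.exists(meta_path) || !file.exists(csv_path)) {
    stn_error(sprintf("no recording container at base path '%s'.", path),
              "stnlfp_io_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$schema) || !identical(meta$schema, RECORDING_SCHEMA)) {
    stn_error(sprintf("unknown recording schema version: '%s'.",
                      meta$schema %||% "<absent>"),
              "stnlfp_schema_error")
  }
  # base read.csv: correctly rounded strtod, so %.17g round-trips bit-exactly
  ch <- utils::read.csv(csv_path, colClasses = "numeric")
  if (ncol(ch) != 3) {
    stn_error(sprintf("a recording must have exactly 3 channels, got %d.",
                      ncol(ch)),
              "stnlfp_channel_count_error")
  }
  if (!is.null(meta$n_samples) && nrow(ch) != meta$n_samples) {
    stn_error("channel length disagrees with container metadata.",
              "stnlfp_channel_length_error")
  }
  recording(as.matrix(ch), fs_raw = meta$fs_raw, subject_id = meta$subject_id,
            hemisphere = meta$hemisphere, subregion = meta$subregion,
            t0 = meta$t0)
}

#' Write / read a Simon-task trial table
#'
#' Trial tables are UTF-8 CSV files with a leading `#schema:` comment line as
#' a version tag. Reading validates the full schema, including the
#' correspondence consistency invariant, via [validate_trials()].
#'
#' @param trials A trial table (see [simulate_behavior()]).
#' @param path Output `.csv` path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` returns
#'   a validated tibble.
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  # doubles at full precision so the round trip is exact
  out <- dplyr::mutate(trials, dplyr::across(
    dplyr::where(is.double),
    function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  ))
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#schema:", TRIALS_SCHEMA), con)
  readr::write_csv(out, con, progress = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) {
    stn_error(sprintf("no trial table at '%s'.", path), "stnlfp_io_error")
  }
  first <- readLines(path, n = 1L)
  tag <- sub("^#schema:", "", first)
  if (identical(tag, first) || !identical(tag, TRIALS_SCHEMA)) {
    stn_error(sprintf("unknown trial-table schema version: '%s'.", first),
              "stnlfp_schema_error")
  }
  trials <- tibble::as_tibble(utils::read.csv(path, comment.char = "#",
                                              stringsAsFactors = FALSE))
  trials <- dplyr::mutate(
    trials,
    dplyr::across(dplyr::any_of(c("stim_onset_s", "rt_ms", "iti_prev_ms")),
                  as.numeric),
    dplyr::across(dplyr::any_of(c("trial_id", "block")), as.integer),
    dplyr::across(dplyr::any_of("response_side"), as.character)
  )
  validate_trials(trials)
}
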