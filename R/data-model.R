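#' Construct a microelectrode recording object
#'
#' A `Recording` holds one depth x hemisphere multichannel raw signal:
#' exactly three parallel microelectrode voltage traces (arbitrary units)
#' with sampling metadata. Three tungsten microelectrodes per hemisphere are
#' advanced together during intraoperative mapping, so three channels is an
#' invariant, not a convention.
#'
#' @param channels A numeric matrix with 3 columns (one per microelectrode),
#'   or a list of 3 equal-length numeric vectors.
#' @param fs_raw Sampling rate in samples/s; must exceed 2 x 100 Hz.
#' @param subject_id Subject identifier string.
#' @param hemisphere `"left"` or `"right"`.
#' @param subregion `"dorsal"` or `"ventral"` STN recording depth.
#' @param t0 Recording start time in seconds (event times in the companion
#'   trial table are on the same clock).
#' @return An object of class `stn_recording`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(3000), ncol = 3), fs_raw = 1000,
#'                  subject_id = "s01", hemisphere = "left",
#'                  subregion = "dorsal")
recording <- function(channels, fs_raw, subject_id, hemisphere, subregion,
                      t0 = 0) {
  if (is.list(channels) && !is.matrix(channels)) {
    lens <- lengths(channels)
    if (length(channels) == 3 && length(unique(lens)) != 1) {
      stn_error("recording channels must have equal length.",
                "stnlfp_channel_length_error")
    }
    channels <- do.call(cbind, channels)
  }
  if (!is.matrix(channels) || !is.numeric(channels)) {
    stn_error("`channels` must be a numeric matrix or list of numeric vectors.",
              "stnlfp_channel_error")
  }
  if (ncol(channels) != 3) {
    stn_error(sprintf("a recording must have exactly 3 channels, got %d.",
                      ncol(channels)),
              "stnlfp_channel_count_error")
  }
  if (!all(is.finite(channels))) {
    stn_error("recording channels must contain finite values only.",
              "stnlfp_channel_error")
  }
  if (fs_raw <= 200) {
    stn_error("`fs_raw` must exceed 2 x 100 Hz.", "stnlfp_config_error")
  }
  check_label(hemisphere, SIDES, "hemisphere")
  check_label(subregion, SUBREGIONS, "subregion")
  colnames(channels) <- paste0("ch", 1:3)
  structure(
    list(subject_id = as.character(subject_id), hemisphere = hemisphere,
         subregion = subregion, channels = channels, fs_raw = as.numeric(fs_raw),
         t0 = as.numeric(t0)),
    class = "stn_recording"
  )
}

#' @export
print.stn_recording <- function(x, ...) {
  cat(sprintf(
    "<stn_recording> %s %s %s: 3 x %d samples @ %g Hz (%.1f s), t0 = %g s\n",
    x$subject_id, x$hemisphere, x$subregion, nrow(x$channels), x$fs_raw,
    nrow(x$channels) / x$fs_raw, x$t0))
  invisible(x)
}

#' Classify a Simon trial as corresponding or non-corresponding
#'
#' A trial is corresponding (`"Cs"`) when the stimulus appears on the same
#' side as the response its colour demands, and non-corresponding (`"NC"`)
#' otherwise; NC trials put the location-driven response impulse in conflict
#' with the colour rule.
#'
#' @param stim_side,correct_side `"left"` or `"right"` (vectorised; recycled
#'   to a common length).
#' @return A character vector of `"Cs"`/`"NC"`.
#' @export
#' @examples
#' classify_correspondence("left", "left")   # "Cs"
#' classify_correspondence("left", "right")  # "NC"
classify_correspondence <- function(stim_side, correct_side) {
  check_labels(stim_side, SIDES, "stim_side")
  check_labels(correct_side, SIDES, "correct_side")
  ifelse(stim_side == correct_side, "Cs", "NC")
}

#' Relabel a recording hemisphere relative to the responding hand
#'
#' Hemisphere is analyzed relative to response-hand laterality: a recording
#' is ipsilateral to a given response when the recorded hemisphere and the
#' responding hand are on the same side.
#'
#' @param recording_hemisphere,response_side `"left"` or `"right"`
#'   (vectorised; recycled to a common length).
#' @return A character vector of `"ipsilateral"`/`"contralateral"`.
#' @export
#' @examples
#' relabel_hemisphere("left", "left")   # "ipsilateral"
#' relabel_hemisphere("left", "right")  # "contralateral"
relabel_hemisphere <- function(recording_hemisphere, response_side) {
  check_labels(recording_hemisphere, SIDES, "recording_hemisphere")
  check_labels(response_side, SIDES, "response_side")
  ifelse(recording_hemisphere == response_side, "ipsilateral", "contralateral")
}

#' Validate a Simon-task trial table
#'
#' Checks the per-trial event schema: required columns, label domains, the
#' correspondence consistency rule (`Cs` iff `stim_side == correct_side`),
#' response-deadline and intertrial-interval ranges, and that responded
#' trials carry a reaction time.
#'
#' @param trials A data frame of per-trial events (see [simulate_behavior()]
#'   for the column set).
#' @return The validated table as a tibble (invisibly usable in a pipe).
#' @export
validate_trials <- function(trials) {
  trials <- tibble::as_tibble(trials)
  required <- c("trial_id", "block", "depth", "stim_onset_s", "stim_side",
                "correct_side", "response_side", "rt_ms", "correspondence",
                "accuracy", "iti_prev_ms")
  missing <- setdiff(required, names(trials))
  if (length(missing)) {
    stn_error(paste0("trial table is missing columns: ",
                     paste(missing, collapse = ", ")),
              "stnlfp_schema_error")
  }
  check_labels(trials$depth, SUBREGIONS, "depth")
  check_labels(trials$stim_side, SIDES, "stim_side")
  check_labels(trials$correct_side, SIDES, "correct_side")
  check_labels(trials$accuracy, ACCURACY_LEVELS, "accuracy")
  check_labels(trials$correspondence, CORRESPONDENCE, "correspondence")
  resp <- !is.na(trials$response_side)
  check_labels(trials$response_side[resp], SIDES, "response_side")
  expected <- classify_correspondence(trials$stim_side, trials$correct_side)
  if (any(expected != trials$correspondence)) {
    stn_error("correspondence labels are inconsistent with stim/correct sides.",
              "stnlfp_consistency_error")
  }
  responded <- trials$accuracy %in% c("correct", "error")
  if (any(responded & is.na(trials$rt_ms))) {
    stn_error("responded trials must have a reaction time.",
              "stnlfp_consistency_error")
  }
  if (any(trials$rt_ms[responded] > 1000, na.rm = TRUE)) {
    stn_error("responded trials cannot exceed the 1000 ms deadline.",
              "stnlfp_consistency_error")
  }
  if (any(responded & trials$accuracy == "correct" &
            trials$response_side != trials$correct_side, na.rm = TRUE)) {
    stn_error("trials marked correct must respond on the correct side.",
              "stnlfp_consistency_error")
  }
  trials
}
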