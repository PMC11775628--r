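#' Select the analysis channel by trial-period variability
#'
#' From the three microelectrode channels, selects the one with the largest
#' variance over the concatenation of all trial periods (stimulus onset to
#' response, responded trials at this recording's depth). Ties break to the
#' lowest channel index.
#'
#' @param rec An [recording()].
#' @param trials Trial table whose `depth` matches `rec$subregion`;
#'   stimulus-onset times are on the recording's clock.
#' @return The selected channel index (1--3), with the per-channel
#'   trial-period variances attached as attribute `"variances"`.
#' @export
select_channel <- function(rec, trials) {
  stopifnot(inherits(rec, "stn_recording"))
  trials <- trials[trials$depth == rec$subregion & !is.na(trials$rt_ms), ,
                   drop = FALSE]
  fs <- rec$fs_raw
  n <- nrow(rec$channels)
  idx <- integer(0)
  for (i in seq_len(nrow(trials))) {
    i0 <- floor((trials$stim_onset_s[i] - rec$t0) * fs) + 1L
    i1 <- ceiling((trials$stim_onset_s[i] + trials$rt_ms[i] / 1000 - rec$t0) * fs)
    i0 <- max(1L, i0); i1 <- min(n, i1)
    if (i1 > i0) idx <- c(idx, i0:i1)
  }
  if (length(idx) < 2) {
    stn_error("no trial period overlaps the recording.",
              "stnlfp_no_overlap_error")
  }
  v <- apply(rec$channels[idx, , drop = FALSE], 2, var)
  structure(which.max(v), variances = unname(v))
}

#' Common-average reference across the three channels
#'
#' Subtracts, at every sample, the cross-channel mean from each channel, so
#' the common-mode component (shared noise, line pickup) is removed and the
#' output cross-channel mean is identically zero.
#'
#' @param rec An [recording()].
#' @return The demeaned [recording()].
#' @export
demean_channels <- function(rec) {
  stopifnot(inherits(rec, "stn_recording"))
  if (ncol(rec$channels) != 3) {
    stn_error("demeaning requires exactly 3 channels.",
              "stnlfp_channel_count_error")
  }
  rec$channels <- rec$channels - rowMeans(rec$channels)
  rec
}

#' Greedy factorization of a decimation ratio into stages <= 13
#' @noRd
decimation_stages <- function(q) {
  stages <- integer(0)
  while (q > 13) {
    d <- max(which(q %% (2:13) == 0)) + 1L
    if (length(d) == 0 || is.infinite(d)) {
      stn_error(sprintf("cannot factor decimation ratio %d into stages <= 13.", q),
                "stnlfp_config_error")
    }
    stages <- c(stages, d)
    q <- q %/% d
  }
  c(stages, q)
}

#' Condition a raw trace to the analysis rate
#'
#' Applies the conditioning chain in order: anti-aliased decimation to
#' `fs_target` (staged integer decimation, or polyphase rational resampling
#' when the ratio is not an integer), linear detrending, a 2nd-order
#' Butterworth band-pass (1--100 Hz by default) and a 2nd-order band-stop
#' notch (59--61 Hz), both applied forward-backward so the chain is
#' zero-phase.
#'
#' @param x Numeric trace sampled at `fs_raw`.
#' @param fs_raw Input sampling rate, samples/s; must exceed 2 x 100 Hz.
#' @param config An [preproc_config()].
#' @return Numeric trace sampled at `config$fs_target`.
#' @export
condition_signal <- function(x, fs_raw, config = preproc_config()) {
  stopifnot(inherits(config, "stn_preproc_config"))
  if (fs_raw <= 200) {
    stn_error("`fs_raw` must exceed 2 x 100 Hz.", "stnlfp_config_error")
  }
  fs <- config$fs_target
  if (fs_raw != fs) {
    ratio <- fs_raw / fs
    if (abs(ratio - round(ratio)) < 1e-9) {
      for (q in decimation_stages(as.integer(round(ratio)))) {
        x <- signal::decimate(x, q, ftype = "iir")
      }
    } else {
      g <- gcd_int(round(fs_raw), round(fs))
      x <- signal::resample(x, round(fs) / g, round(fs_raw) / g)
    }
  }
  t <- seq_along(x)
  fit <- stats::lm.fit(cbind(1, t), x)
  x <- fit$residuals
  bp <- signal::butter(config$order, config$bandpass / (fs / 2), type = "pass")
  x <- signal::filtfilt(bp, x)
  notch <- signal::butter(config$order, config$notch / (fs / 2), type = "stop")
  signal::filtfilt(notch, x)
}

#' @noRd
gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
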