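#' Wavelet cycles for each analyzed frequency (linear 4 -> 12 ramp)
#' @noRd
cycle_ramp <- function(freqs, cycles_range = c(4, 12)) {
  if (length(freqs) == 1 || diff(range(freqs)) == 0) {
    return(rep(mean(cycles_range), length(freqs)))
  }
  cycles_range[1] + (cycles_range[2] - cycles_range[1]) *
    (freqs - min(freqs)) / (max(freqs) - min(freqs))
}

#' Morlet wavelet time-frequency power
#'
#' FFT-based complex Morlet decomposition: for each analyzed frequency the
#' trace is convolved with a Gaussian-windowed complex sinusoid and the
#' squared magnitude taken. The number of cycles ramps linearly from
#' `cycles_range[1]` at the lowest analyzed frequency to `cycles_range[2]`
#' at the highest, trading temporal precision at low frequencies for
#' spectral precision at high ones. The convolution is computed in the
#' frequency domain with the wavelet's spectrum peak-normalized to 1
#' (one-sided, factor 2), so a unit-amplitude sinusoid at an analyzed
#' frequency yields power 1.
#'
#' Samples within half a wavelet length (3.5 Gaussian SDs) of either end are
#' contaminated by edge effects; their count per frequency is returned in
#' the `edge` field.
#'
#' @param x Numeric trace at `fs` samples/s; must be longer than the longest
#'   wavelet (7 SDs at the lowest frequency).
#' @param fs Sampling rate in samples/s (the analysis rate, 1000).
#' @param config An [tf_config()] supplying `freqs` and `cycles_range`.
#' @return An object of class `stn_tfr`: list with `power` (frequency x time
#'   matrix), `freqs`, `fs`, `cycles`, and `edge` (per-frequency count of
#'   edge-contaminated samples at each end).
#' @export
#' @examples
#' x <- sin(2 * pi * 5 * seq(0, 10, by = 1e-3))
#' tfr <- morlet_power(x, 1000, tf_config(freqs = 2:30))
#' which.max(rowMeans(tfr$power))  # peaks at 5 Hz
morlet_power <- function(x, fs, config = tf_config()) {
  stopifnot(inherits(config, "stn_tf_config"))
  freqs <- config$freqs
  cycles <- cycle_ramp(freqs, config$cycles_range)
  sigma_t <- cycles / (2 * pi * freqs)
  half_len <- ceiling(3.5 * sigma_t * fs)
  n <- length(x)
  if (n <= 2 * max(half_len)) {
    stn_error(sprintf(
      "trace (%d samples) is shorter than the longest wavelet support (%d samples).",
      n, 2 * max(half_len)),
      "stnlfp_wavelet_support_error")
  }
  nfft <- stats::nextn(n + 2 * max(half_len), 2)
  X <- fft(c(x, numeric(nfft - n)))
  fgrid <- (seq_len(nfft) - 1) / nfft * fs
  pos <- fgrid <= fs / 2            # analytic: keep positive frequencies only
  power <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    sigma_f <- freqs[i] / cycles[i]
    W <- numeric(nfft)
    W[pos] <- 2 * exp(-(fgrid[pos] - freqs[i])^2 / (2 * sigma_f^2))
    y <- fft(X * W, inverse = TRUE)[seq_len(n)] / nfft
    power[i, ] <- Re(y)^2 + Im(y)^2
  }
  structure(
    list(power = power, freqs = freqs, fs = fs, cycles = cycles,
         edge = half_len),
    class = "stn_tfr"
  )
}

#' Band power time series
#'
#' Mean power across the frequency rows falling inside the band (inclusive
#' bounds).
#'
#' @param tfr An `stn_tfr` from [morlet_power()], or a frequency x time
#'   power matrix (then `freqs` must be given).
#' @param band Two-element band limits in Hz (e.g. `c(4, 7)` theta,
#'   `c(12, 22)` low beta).
#' @param freqs Row frequencies when `tfr` is a plain matrix.
#' @return Numeric band-power time series.
#' @export
band_power <- function(tfr, band, freqs = NULL) {
  if (inherits(tfr, "stn_tfr")) {
    freqs <- tfr$freqs
    power <- tfr$power
  } else {
    power <- tfr
    if (is.null(freqs)) {
      stn_error("`freqs` is required when `tfr` is a plain matrix.",
                "stnlfp_config_error")
    }
  }
  rows <- freqs >= band[1] & freqs <= band[2]
  if (!any(rows)) {
    stn_error(sprintf("band [%g, %g] Hz lies outside the analyzed frequencies.",
                      band[1], band[2]),
              "stnlfp_band_error")
  }
  colMeans(power[rows, , drop = FALSE])
}

#' Decibel normalization against a baseline
#'
#' `10 * log10(power / mean(baseline_power))`: 0 dB means equal to the
#' baseline mean, +10 dB a tenfold increase.
#'
#' @param epoch_power Power samples to normalize.
#' @param baseline_power Baseline power samples (their mean is the
#'   reference; must be positive).
#' @return Numeric dB series.
#' @export
#' @examples
#' db_normalize(c(1, 10, 0.5), rep(1, 380))  # 0, 10, ~-3.01 dB
db_normalize <- function(epoch_power, baseline_power) {
  m <- mean(baseline_power)
  if (!is.finite(m) || m <= 0) {
    stn_error("baseline mean power must be positive for dB normalization.",
              "stnlfp_numeric_error")
  }
  10 * log10(epoch_power / m)
}

#' Z-score power against a baseline
#'
#' `(power - mean(baseline)) / sd(baseline)`. In the pipeline the baseline
#' mean and SD are pooled over all of a subject's baseline windows within
#' subregion x band; pass them via `center`/`scale` to use pooled moments.
#'
#' @param epoch_power Power samples to normalize.
#' @param baseline_power Baseline power samples.
#' @param center,scale Optional pooled baseline mean and SD overriding the
#'   moments of `baseline_power`.
#' @return Numeric z-scored series.
#' @export
zscore_epoch <- function(epoch_power, baseline_power, center = NULL,
                         scale = NULL) {
  m <- center %||% mean(baseline_power)
  s <- scale %||% sd(baseline_power)
  if (!is.finite(s) || s <= 0) {
    stn_error("baseline SD must be positive for z-scoring.",
              "stnlfp_numeric_error")
  }
  (epoch_power - m) / s
}

#' Trial inclusion test against the baseline
#'
#' A trial enters the statistical analysis only when its analysis-window
#' power differs significantly from its baseline-window power: a two-sided
#' paired t-test on the samplewise differences of the two equal-length
#' windows, included iff `p < qc_alpha`.
#'
#' @param epoch_power,baseline_power Equal-length power windows (380 samples
#'   at 1000 Hz in the default configuration).
#' @param qc_alpha Two-sided alpha.
#' @return A one-row tibble: `included`, `t`, `p`, `reason` (`NA` when the
#'   test ran; `"zero_variance"` when the samplewise differences had no
#'   variance, in which case the trial is excluded).
#' @export
qc_trial <- function(epoch_power, baseline_power, qc_alpha = 0.05) {
  if (length(epoch_power) != length(baseline_power)) {
    stn_error("analysis and baseline windows must have equal length.",
              "stnlfp_config_error")
  }
  d <- epoch_power - baseline_power
  if (sd(d) == 0) {
    return(tibble::tibble(included = FALSE, t = NA_real_, p = NA_real_,
                          reason = "zero_variance"))
  }
  tt <- t.test(d)
  tibble::tibble(included = unname(tt$p.value < qc_alpha),
                 t = unname(tt$statistic), p = unname(tt$p.value),
                 reason = NA_character_)
}

#' Average a response-locked series into equal time bins
#'
#' Partitions the analysis window into `n_bins` contiguous, non-overlapping
#' half-open bins (bin 1 earliest) and returns the mean of each.
#'
#' @param z_series Series covering the analysis window (length divisible by
#'   `n_bins`; 380 samples -> four 95 ms bins).
#' @param n_bins Number of bins.
#' @return Named numeric vector of bin means (`bin1` ... ).
#' @export
#' @examples
#' bin_power(seq(0, 1, length.out = 380))  # ~0.125 0.375 0.625 0.875
bin_power <- function(z_series, n_bins = 4) {
  n <- length(z_series)
  if (n == 0 || anyNA(z_series) || n %% n_bins != 0) {
    stn_error("series length must be a positive multiple of `n_bins` with no missing samples.",
              "stnlfp_config_error")
  }
  m <- colMeans(matrix(z_series, ncol = n_bins))
  names(m) <- paste0("bin", seq_len(n_bins))
  m
}

#' Response-locked epoch and baseline sample indices for one trial
#' @noRd
epoch_indices <- function(stim_idx, resp_idx, config) {
  win <- config$analysis_window_ms
  analysis <- (resp_idx + win[1]):(resp_idx + win[2] - 1L)
  if (config$baseline_policy == "intertrial") {
    # baseline ends 100 ms before stimulus onset, inside the preceding ITI
    baseline <- (stim_idx - 100L - config$baseline_len_ms):(stim_idx - 101L)
  } else {
    # literal reading: 500 to 100 ms before the button response
    baseline <- (resp_idx - 100L - config$baseline_len_ms):(resp_idx - 101L)
  }
  list(analysis = analysis, baseline = baseline)
}

#' Extract response-locked band epochs for correct trials
#'
#' Cuts a band-power series (at the analysis rate) into response-locked
#' analysis windows (`[-380, 0)` ms; time 0 = the timestamped button
#' response) and the matching baseline windows, for correct trials only.
#' Error, omission and too-early trials emit no epoch; trials whose windows
#' fall outside the series are dropped with a logged reason.
#'
#' @param band_series Numeric band-power series at `fs` samples/s, sample 1
#'   at the recording's `t0`.
#' @param trials Trial table on the same clock (rows at one depth).
#' @param config An [tf_config()] (analysis window and baseline policy).
#' @param fs Sampling rate of `band_series`.
#' @return A list with `epochs` (tibble: `trial_id`, `correspondence`,
#'   `response_side`, `epoch` and `baseline` list-columns) and `dropped`
#'   (tibble: `trial_id`, `reason`).
#' @export
extract_epochs <- function(band_series, trials, config = tf_config(),
                           fs = 1000) {
  stopifnot(inherits(config, "stn_tf_config"))
  n <- length(band_series)
  rows <- vector("list", nrow(trials))
  dropped <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    if (tr$accuracy != "correct") {
      dropped[[i]] <- tibble::tibble(trial_id = tr$trial_id,
                                     reason = "not_correct")
      next
    }
    stim_idx <- round(tr$stim_onset_s * fs) + 1L
    resp_idx <- round((tr$stim_onset_s + tr$rt_ms / 1000) * fs) + 1L
    idx <- epoch_indices(stim_idx, resp_idx, config)
    if (min(idx$analysis, idx$baseline) < 1 ||
        max(idx$analysis, idx$baseline) > n) {
      dropped[[i]] <- tibble::tibble(trial_id = tr$trial_id,
                                     reason = "out_of_bounds")
      next
    }
    rows[[i]] <- tibble::tibble(
      trial_id = tr$trial_id, correspondence = tr$correspondence,
      response_side = tr$response_side,
      epoch = list(band_series[idx$analysis]),
      baseline = list(band_series[idx$baseline])
    )
  }
  list(epochs = dplyr::bind_rows(rows), dropped = dplyr::bind_rows(dropped))
}
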