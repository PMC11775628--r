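#' Simulation configuration for synthetic Simon-task STN recordings
#'
#' Parameterizes the synthetic cohort generator: intraoperative microelectrode
#' recordings (three channels per hemisphere at two STN depths) and the
#' time-locked Simon-task event stream. Defaults follow the intraoperative
#' study design the pipeline targets: 10 subjects, 144 trials per block, two
#' blocks per depth, a 1000 ms response deadline and a 750--1250 ms variable
#' intertrial interval. Oscillatory effect sizes are calibrated so that
#' pipeline recovery is testable at desk scale, not to match patient
#' physiology (no physical-unit effect sizes are available for the latter).
#'
#' @param n_subjects Number of subjects in a simulated cohort.
#' @param trials_per_block Trials per task block. The study design uses
#'   144--190; smaller values (>= 8) are accepted for fast tests.
#' @param blocks_per_depth Task blocks recorded at each STN depth.
#' @param fs_raw Raw sampling rate in samples/s. The acquisition-scale value
#'   is 44000; the default 11000 keeps simulation desk-scale. Any rate
#'   > 2 x 100 Hz that decimates or resamples cleanly to 1000 Hz works.
#' @param pink_exponent Slope of the 1/f background noise spectrum.
#' @param line_amp Amplitude of the common-mode 60 Hz line component, in
#'   units of the background-noise standard deviation.
#' @param theta_base,beta_base Baseline amplitudes of the response-locked
#'   theta (4--7 Hz) and low-beta (12--22 Hz) bursts, in noise-SD units.
#' @param theta_bg,beta_bg Amplitudes of the ongoing (non-burst) narrowband
#'   theta/beta background present throughout the recording, including the
#'   intertrial baseline window.
#' @param effect_theta_dorsal_NC Multiplicative theta burst gain applied on
#'   dorsal non-corresponding (NC) trials. 1 = no conflict effect.
#' @param effect_beta_ipsi_NC Multiplicative beta burst gain applied in the
#'   hemisphere ipsilateral to the response on NC trials.
#' @param effect_beta_dorsal Multiplicative beta gain (bursts and background)
#'   in dorsal recordings, emulating elevated dorsal beta.
#' @param subject_sd Standard deviation of the subject-level log-amplitude
#'   random intercept shared across that subject's recordings.
#' @param rt_mu,rt_sigma,rt_tau Ex-Gaussian reaction-time parameters (ms) for
#'   corresponding (Cs) trials.
#' @param simon_rt_shift_ms Mean NC - Cs reaction-time cost in ms.
#' @param late_suppression Strength (0--1) of selective suppression of the
#'   Simon RT cost on slow trials; > 0 yields a negative-going final delta
#'   slope.
#' @param p_impulse_error Probability that a fast automatic response capture
#'   on an NC trial is committed as an error (the impulse-capture race).
#' @param p_impulse_sd Log-scale between-subject spread of the impulse-capture
#'   probability (drives individual differences in the accuracy Simon effect).
#' @param p_lapse Condition-independent lapse (wrong-key) probability.
#' @param p_anticipatory Probability of an anticipatory fast guess
#'   (RT < 150 ms, random side).
#' @param baseline_beta_behavior_rho Target monotone (Spearman) coupling
#'   between a subject's ventral baseline beta level and their accuracy Simon
#'   effect, implemented by rank-coupling the subject-level beta intercepts to
#'   the subject-level impulse-capture probabilities through a Gaussian
#'   copula.
#' @param seed RNG seed; identical configurations produce identical cohorts.
#'
#' @return A list of class `stn_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 2, trials_per_block = 16, fs_raw = 2000)
#' trials <- simulate_behavior(cfg)
sim_config <- function(n_subjects = 10,
                       trials_per_block = 144,
                       blocks_per_depth = 2,
                       fs_raw = 11000,
                       pink_exponent = 1,
                       line_amp = 0.5,
                       theta_base = 1.6,
                       beta_base = 1.6,
                       theta_bg = 0.35,
                       beta_bg = 0.35,
                       effect_theta_dorsal_NC = 1.5,
                       effect_beta_ipsi_NC = 1.4,
                       effect_beta_dorsal = 1.2,
                       subject_sd = 0.2,
                       rt_mu = 450,
                       rt_sigma = 60,
                       rt_tau = 120,
                       simon_rt_shift_ms = 40,
                       late_suppression = 0,
                       p_impulse_error = 0.08,
                       p_impulse_sd = 0.8,
                       p_lapse = 0.1,
                       p_anticipatory = 0.01,
                       baseline_beta_behavior_rho = 0.8,
                       seed = 1L) {
  check_positive(n_subjects, "n_subjects")
  if (trials_per_block < 8) {
    stn_error("`trials_per_block` must be at least 8.", "stnlfp_config_error")
  }
  check_positive(blocks_per_depth, "blocks_per_depth")
  if (fs_raw <= 200) {
    stn_error("`fs_raw` must exceed 2 x 100 Hz.", "stnlfp_config_error")
  }
  for (nm in c("line_amp", "theta_base", "beta_base", "theta_bg", "beta_bg",
               "effect_theta_dorsal_NC", "effect_beta_ipsi_NC",
               "effect_beta_dorsal", "subject_sd", "late_suppression")) {
    check_positive(get(nm), nm, strict = FALSE)
  }
  for (nm in c("p_impulse_error", "p_lapse", "p_anticipatory")) {
    p <- get(nm)
    if (!is.numeric(p) || p < 0 || p > 1) {
      stn_error(sprintf("`%s` must be a probability in [0, 1].", nm),
                "stnlfp_config_error")
    }
  }
  if (abs(baseline_beta_behavior_rho) > 1) {
    stn_error("`baseline_beta_behavior_rho` must lie in [-1, 1].",
              "stnlfp_config_error")
  }
  if (rt_mu >= 1000) {
    stn_error("`rt_mu` must be below the 1000 ms response deadline.",
              "stnlfp_config_error")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      trials_per_block = as.integer(trials_per_block),
      blocks_per_depth = as.integer(blocks_per_depth),
      fs_raw = fs_raw,
      pink_exponent = pink_exponent,
      line_amp = line_amp,
      theta_base = theta_base,
      beta_base = beta_base,
      theta_bg = theta_bg,
      beta_bg = beta_bg,
      effect_theta_dorsal_NC = effect_theta_dorsal_NC,
      effect_beta_ipsi_NC = effect_beta_ipsi_NC,
      effect_beta_dorsal = effect_beta_dorsal,
      subject_sd = subject_sd,
      rt_mu = rt_mu,
      rt_sigma = rt_sigma,
      rt_tau = rt_tau,
      simon_rt_shift_ms = simon_rt_shift_ms,
      late_suppression = late_suppression,
      p_impulse_error = p_impulse_error,
      p_impulse_sd = p_impulse_sd,
      p_lapse = p_lapse,
      p_anticipatory = p_anticipatory,
      baseline_beta_behavior_rho = baseline_beta_behavior_rho,
      seed = as.integer(seed)
    ),
    class = "stn_sim_config"
  )
}

#' Null-effect variant of a simulation configuration
#'
#' Convenience wrapper setting every condition effect to its null value
#' (unit gains, zero RT shift, no impulse capture, no baseline/behavior
#' coupling) while keeping the noise and subject-variability structure.
#' Used for type-I-error calibration.
#'
#' @param ... Passed on to [sim_config()].
#' @return An `stn_sim_config`.
#' @export
null_sim_config <- function(...) {
  sim_config(
    effect_theta_dorsal_NC = 1, effect_beta_ipsi_NC = 1, effect_beta_dorsal = 1,
    simon_rt_shift_ms = 0, late_suppression = 0,
    p_impulse_error = 0, baseline_beta_behavior_rho = 0, ...
  )
}

#' Signal-conditioning configuration
#'
#' The raw-signal conditioning chain: anti-aliased decimation to `fs_target`,
#' linear detrending, a 2nd-order Butterworth band-pass and a 2nd-order
#' band-stop (notch), both applied forward-backward (zero-phase) so that
#' response-locked timing is not skewed by group delay.
#'
#' @param fs_target Target sampling rate, samples/s.
#' @param bandpass Two-element band-pass corner frequencies in Hz.
#' @param notch Two-element band-stop corner frequencies in Hz.
#' @param order Butterworth filter order for both filters.
#' @return A list of class `stn_preproc_config`.
#' @export
preproc_config <- function(fs_target = 1000,
                           bandpass = c(1, 100),
                           notch = c(59, 61),
                           order = 2) {
  check_positive(fs_target, "fs_target")
  stopifnot(length(bandpass) == 2, length(notch) == 2, order >= 1)
  if (bandpass[2] >= fs_target / 2) {
    stn_error("band-pass upper corner must be below fs_target / 2.",
              "stnlfp_config_error")
  }
  structure(
    list(fs_target = fs_target, bandpass = as.numeric(bandpass),
         notch = as.numeric(notch), order = as.integer(order)),
    class = "stn_preproc_config"
  )
}

#' Time-frequency analysis configuration
#'
#' Morlet wavelet decomposition with a linear cycle ramp (4 cycles at the
#' lowest analyzed frequency up to 12 at the highest), theta and low-beta
#' band definitions, the response-locked analysis window, time binning, the
#' baseline policy, and the trial-inclusion (QC) alpha.
#'
#' `baseline_policy` resolves an ambiguity in how the 380 ms baseline is
#' placed: `"intertrial"` (default) takes 380 ms ending 100 ms before the
#' stimulus onset, inside the preceding intertrial interval, so baseline and
#' analysis windows never overlap; `"literal_preresponse"` takes the window
#' 500 to 100 ms *before the response* ([-480, -100) ms), which can overlap
#' the analysis window on fast trials.
#'
#' @param freqs Analyzed frequencies in Hz (default 2--100 in 1 Hz steps).
#' @param cycles_range Wavelet cycles at the lowest and highest analyzed
#'   frequency; cycles ramp linearly in frequency between the two.
#' @param theta_band,beta_band Inclusive band limits in Hz.
#' @param analysis_window_ms Half-open response-locked analysis window
#'   `[a, b)` in ms (0 = timestamped button response).
#' @param n_bins Number of equal time bins partitioning the analysis window.
#' @param baseline_policy `"intertrial"` or `"literal_preresponse"`.
#' @param baseline_len_ms Baseline window length in ms.
#' @param qc_alpha Two-sided alpha for the paired-t trial inclusion test.
#' @param qc_band `"broadband"` (default; QC on the mean power across all
#'   analyzed frequencies) or `"per_band"` (QC on the band's own power).
#' @return A list of class `stn_tf_config`.
#' @export
tf_config <- function(freqs = 2:100,
                      cycles_range = c(4, 12),
                      theta_band = c(4, 7),
                      beta_band = c(12, 22),
                      analysis_window_ms = c(-380, 0),
                      n_bins = 4,
                      baseline_policy = c("intertrial", "literal_preresponse"),
                      baseline_len_ms = 380,
                      qc_alpha = 0.05,
                      qc_band = c("broadband", "per_band")) {
  baseline_policy <- match.arg(baseline_policy)
  qc_band <- match.arg(qc_band)
  freqs <- sort(unique(as.numeric(freqs)))
  stopifnot(length(freqs) >= 1, all(freqs > 0), length(cycles_range) == 2)
  win_len <- diff(analysis_window_ms)
  if (win_len <= 0 || win_len %% n_bins != 0) {
    stn_error("analysis window length must be positive and divisible by `n_bins`.",
              "stnlfp_config_error")
  }
  for (band in list(theta_band, beta_band)) {
    if (band[1] < min(freqs) || band[2] > max(freqs)) {
      stn_error("frequency bands must lie within the analyzed frequency range.",
                "stnlfp_config_error")
    }
  }
  structure(
    list(freqs = freqs, cycles_range = as.numeric(cycles_range),
         theta_band = as.numeric(theta_band), beta_band = as.numeric(beta_band),
         analysis_window_ms = as.numeric(analysis_window_ms),
         n_bins = as.integer(n_bins), baseline_policy = baseline_policy,
         baseline_len_ms = baseline_len_ms, qc_alpha = qc_alpha,
         qc_band = qc_band),
    class = "stn_tf_config"
  )
}

#' Mixed-model specification for band-power analysis
#'
#' Fixed effects: STN subregion, correspondence, hemisphere (relative to the
#' responding hand), the subregion x correspondence and hemisphere x
#' correspondence two-way interactions, and the three-way interaction
#' (the subregion x hemisphere two-way is deliberately absent, which gives
#' the three-way term 2 numerator df). Random effects: an intercept per
#' subject, a random slope for time bin nested within correspondence within
#' subregion, and a random slope for correspondence. Time bin enters the
#' random part only.
#'
#' @param alpha Two-sided significance level.
#' @param random `"full"` for the structure above, `"no_time"` to drop the
#'   nested time slope, `"intercept"` for a subject intercept only. `fit_mixed()`
#'   starts at `random` and steps down this ladder on convergence failure.
#' @return A list of class `stn_model_spec`.
#' @export
model_spec <- function(alpha = 0.05, random = c("full", "no_time", "intercept")) {
  random <- match.arg(random)
  structure(list(alpha = alpha, random = random), class = "stn_model_spec")
}

#' Full pipeline run configuration
#'
#' Bundles the per-stage configurations and the seed; a pipeline run is
#' reproducible from this object alone.
#'
#' @param sim An [sim_config()] (simulation mode), or `NULL` when ingesting
#'   previously written containers via `in_dir`.
#' @param preproc An [preproc_config()].
#' @param tf An [tf_config()].
#' @param model An [model_spec()].
#' @param seed Integer seed overriding `sim$seed` when given.
#' @param in_dir Optional directory of containers written by
#'   [write_recording()] / [write_trials()] (real-data mode).
#' @return A list of class `stn_run_config`.
#' @export
run_config <- function(sim = sim_config(),
                       preproc = preproc_config(),
                       tf = tf_config(),
                       model = model_spec(),
                       seed = NULL,
                       in_dir = NULL) {
  if (!is.null(sim) && !inherits(sim, "stn_sim_config")) {
    stn_error("`sim` must be created by sim_config().", "stnlfp_config_error")
  }
  if (!is.null(seed) && !is.null(sim)) sim$seed <- as.integer(seed)
  structure(
    list(sim = sim, preproc = preproc, tf = tf, model = model,
         seed = if (is.null(seed)) sim$seed else as.integer(seed),
         in_dir = in_dir),
    class = "stn_run_config"
  )
}
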