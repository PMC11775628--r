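test_that("behavioral generator respects the task design", {
  trials <- simulate_behavior(sim_config(trials_per_block = 145, seed = 3))
  # correspondence balanced to within one trial per block
  bal <- trials |>
    dplyr::count(.data$depth, .data$block, .data$correspondence) |>
    tidyr::pivot_wider(names_from = "correspondence", values_from = "n")
  expect_true(all(abs(bal$Cs - bal$NC) <= 1))
  # ITI range and response deadline
  expect_true(all(trials$iti_prev_ms >= 750 & trials$iti_prev_ms <= 1250))
  responded <- trials$accuracy %in% c("correct", "error")
  expect_true(all(trials$rt_ms[responded] <= 1000))
  expect_true(all(is.na(trials$rt_ms[trials$accuracy %in%
                                       c("omission", "too_early")])))
  # infeasible configuration is rejected
  expect_error(sim_config(rt_mu = 1200), class = "stnlfp_config_error")
})

test_that("null behavioral configuration has no Simon effect", {
  cfg <- sim_config(trials_per_block = 180, blocks_per_depth = 14,
                    simon_rt_shift_ms = 0, p_impulse_error = 0, seed = 11)
  trials <- simulate_behavior(cfg)
  correct <- trials[trials$accuracy == "correct", ]
  diff_rt <- mean(correct$rt_ms[correct$correspondence == "NC"]) -
    mean(correct$rt_ms[correct$correspondence == "Cs"])
  expect_lt(abs(diff_rt), 8)   # ~3 SE at this trial count
  acc <- trials |>
    dplyr::filter(.data$accuracy %in% c("correct", "error")) |>
    dplyr::group_by(.data$correspondence) |>
    dplyr::summarise(acc = mean(.data$accuracy == "correct"))
  expect_lt(abs(diff(acc$acc)), 0.02)
})

test_that("generated Simon RT cost recovers the configured shift", {
  # >= 10000 trials, impulse capture off so the correct-trial means are unbiased
  cfg <- sim_config(trials_per_block = 180, blocks_per_depth = 28,
                    simon_rt_shift_ms = 40, p_impulse_error = 0, seed = 21)
  trials <- simulate_behavior(cfg)
  expect_gte(nrow(trials), 10000)
  correct <- trials[trials$accuracy == "correct", ]
  diff_rt <- mean(correct$rt_ms[correct$correspondence == "NC"]) -
    mean(correct$rt_ms[correct$correspondence == "Cs"])
  expect_lt(abs(diff_rt - 40), 5)
})

test_that("impulse capture concentrates NC errors in the fastest bin", {
  cfg <- sim_config(trials_per_block = 180, blocks_per_depth = 4,
                    p_impulse_error = 0.3, seed = 31)
  trials <- simulate_behavior(cfg)
  caf <- conditional_accuracy(trim_rts(trials))
  nc <- caf[caf$correspondence == "NC", ] |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(acc = mean(.data$accuracy_pct))
  expect_lt(nc$acc[nc$bin == 1], nc$acc[nc$bin == 4])
})

test_that("recording simulation is seed-deterministic", {
  cfg <- tiny_sim(seed = 7)
  trials <- simulate_behavior(cfg)
  r1 <- simulate_recording(cfg, trials, "dorsal", "left", seed = 99)
  r2 <- simulate_recording(cfg, trials, "dorsal", "left", seed = 99)
  expect_identical(r1$channels, r2$channels)
  r3 <- simulate_recording(cfg, trials, "dorsal", "left", seed = 100)
  expect_false(identical(r1$channels, r3$channels))
})

test_that("degenerate noise configuration gives a flat spectrum", {
  cfg <- tiny_sim(pink_exponent = 0, line_amp = 0, theta_base = 0,
                  beta_base = 0, theta_bg = 0, beta_bg = 0, seed = 13)
  trials <- simulate_behavior(cfg)
  rec <- simulate_recording(cfg, trials, "dorsal", "left")
  x <- rec$channels[, 1]
  # log-log slope of the periodogram should be ~0 for white noise
  n <- length(x)
  X <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) / n * cfg$fs_raw
  keep <- f > 1 & f < 500
  # average the periodogram in octave bands before fitting the slope
  bands <- cut(log10(f[keep]), 20)
  pb <- tapply(X[keep], bands, mean)
  fb <- tapply(log10(f[keep]), bands, mean)
  slope <- coef(lm(log10(pb) ~ fb))[2]
  expect_lt(abs(slope), 0.3)
})

test_that("theta and beta bursts land in their own bands (periodogram oracle)", {
  base <- list(line_amp = 0, theta_bg = 0, beta_bg = 0, seed = 17,
               trials_per_block = 24)
  cfg_t <- do.call(sim_config, c(base, list(theta_base = 15, beta_base = 0,
                                            fs_raw = 2000, n_subjects = 1,
                                            blocks_per_depth = 1)))
  trials <- simulate_behavior(cfg_t)
  rec <- simulate_recording(cfg_t, trials, "dorsal", "left")
  x <- rec$channels[, 1]
  expect_gt(periodogram_band_power(x, 2000, c(4, 7)) /
              periodogram_band_power(x, 2000, c(12, 22)), 5)

  cfg_b <- do.call(sim_config, c(base, list(theta_base = 0, beta_base = 15,
                                            fs_raw = 2000, n_subjects = 1,
                                            blocks_per_depth = 1)))
  rec_b <- simulate_recording(cfg_b, simulate_behavior(cfg_b), "dorsal", "left")
  xb <- rec_b$channels[, 1]
  expect_gt(periodogram_band_power(xb, 2000, c(12, 22)) /
              periodogram_band_power(xb, 2000, c(4, 7)), 5)
})

test_that("dorsal NC theta gain raises pre-response theta power (Welch oracle)", {
  cfg <- sim_config(n_subjects = 1, trials_per_block = 144,
                    blocks_per_depth = 1, fs_raw = 2000,
                    effect_theta_dorsal_NC = 2.0, seed = 23)
  trials <- simulate_behavior(cfg)
  rec <- simulate_recording(cfg, trials, "dorsal", "left")
  correct <- trials[trials$accuracy == "correct" & trials$depth == "dorsal", ]
  pow <- vapply(seq_len(nrow(correct)), function(i) {
    resp <- correct$stim_onset_s[i] + correct$rt_ms[i] / 1000
    idx <- round((resp - 0.380) * 2000):round(resp * 2000)
    periodogram_band_power(rec$channels[idx, 1], 2000, c(4, 7))
  }, numeric(1))
  tt <- t.test(pow[correct$correspondence == "NC"],
               pow[correct$correspondence == "Cs"], alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("cohort assembly is deterministic with shared subject effects", {
  cfg <- tiny_sim(seed = 41)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_equal(co1$subjects, co2$subjects)
  expect_identical(co1$recordings$recording[[3]]$channels,
                   co2$recordings$recording[[3]]$channels)
  # bookkeeping: subjects x 2 hemispheres x 2 depths containers
  expect_equal(nrow(co1$recordings), cfg$n_subjects * 4)
  expect_equal(dplyr::n_distinct(co1$trials$subject_id), cfg$n_subjects)
})

test_that("uncoupled cohorts show no baseline-beta/behavior association", {
  rhos <- vapply(1:60, function(i) {
    co <- simulate_cohort(sim_config(baseline_beta_behavior_rho = 0,
                                     p_impulse_error = 0.25, seed = 7000 + i),
                          signals = FALSE)
    eff <- co$trials |>
      dplyr::filter(.data$accuracy %in% c("correct", "error")) |>
      dplyr::group_by(.data$subject_id, .data$correspondence) |>
      dplyr::summarise(acc = 100 * mean(.data$accuracy == "correct"),
                       .groups = "drop") |>
      tidyr::pivot_wider(names_from = "correspondence", values_from = "acc")
    j <- dplyr::left_join(co$subjects, eff, by = "subject_id")
    cor(j$beta_level, j$Cs - j$NC, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("power-cell emulator reproduces its configured effects in the mean", {
  pc <- simulate_powercells(sim_config(n_subjects = 200, seed = 51))
  th <- pc[pc$band == "theta", ]
  cellmean <- function(d, ...) mean(dplyr::filter(d, ...)$log_power)
  # dorsal NC - dorsal Cs ~ 0.6 * 2 * log(1.5)
  eff <- cellmean(th, .data$subregion == "dorsal", .data$correspondence == "NC") -
    cellmean(th, .data$subregion == "dorsal", .data$correspondence == "Cs")
  expect_lt(abs(eff - 0.6 * 2 * log(1.5)), 0.05)
  be <- pc[pc$band == "beta", ]
  eff_ipsi <- cellmean(be, .data$hemisphere_rel == "ipsilateral",
                       .data$correspondence == "NC") -
    cellmean(be, .data$hemisphere_rel == "ipsilateral",
             .data$correspondence == "Cs")
  expect_lt(abs(eff_ipsi - 0.6 * 2 * log(1.4)), 0.05)
})
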