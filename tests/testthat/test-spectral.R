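test_that("wavelet power is band-selective on pure sinusoids", {
  fs <- 1000
  t <- seq(0, 10, by = 1 / fs)[-1]
  cfg <- tf_config(freqs = 2:30)
  trim <- 2000:8000   # keep clear of wavelet edges

  x5 <- sin(2 * pi * 5 * t)
  # periodogram oracle confirms the input itself is theta-dominated
  expect_gt(periodogram_band_power(x5, fs, c(4, 7)) /
              periodogram_band_power(x5, fs, c(12, 22)), 10)
  tfr <- morlet_power(x5, fs, cfg)
  expect_equal(cfg$freqs[which.max(rowMeans(tfr$power[, trim]))], 5)
  expect_gt(mean(band_power(tfr, cfg$theta_band)[trim]) /
              mean(band_power(tfr, cfg$beta_band)[trim]), 10)

  x18 <- sin(2 * pi * 18 * t)
  tfr18 <- morlet_power(x18, fs, cfg)
  expect_gt(mean(band_power(tfr18, cfg$beta_band)[trim]) /
              mean(band_power(tfr18, cfg$theta_band)[trim]), 10)

  # zero in, zero out
  tfr0 <- morlet_power(numeric(5000), fs, cfg)
  expect_equal(max(abs(tfr0$power)), 0)

  # trace shorter than the wavelet support errors
  expect_error(morlet_power(rnorm(500), fs, cfg),
               class = "stnlfp_wavelet_support_error")
})

test_that("wavelet band power tracks amplitude monotonically (Parseval-style)", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)[-1]
  cfg <- tf_config(freqs = 2:30)
  amps <- c(0.5, 1, 2, 4, 8)
  wp <- pp <- numeric(length(amps))
  for (i in seq_along(amps)) {
    x <- amps[i] * sin(2 * pi * 6 * t)
    wp[i] <- mean(band_power(morlet_power(x, fs, cfg),
                             cfg$theta_band)[1000:3000])
    pp[i] <- periodogram_band_power(x, fs, c(4, 7))
  }
  expect_equal(cor(wp, pp, method = "spearman"), 1)
})

test_that("band power equals the row mean of the map", {
  set.seed(4)
  freqs <- 2:30
  map <- matrix(runif(29 * 50), 29, 50)
  bp <- band_power(map, c(12, 22), freqs = freqs)
  expect_equal(bp, colMeans(map[freqs >= 12 & freqs <= 22, ]))
  # constant map gives a constant series
  expect_equal(band_power(matrix(3, 29, 10), c(4, 7), freqs = freqs),
               rep(3, 10))
  # power only at 5 Hz: theta positive, beta zero
  m5 <- matrix(0, 29, 10); m5[freqs == 5, ] <- 1
  expect_true(all(band_power(m5, c(4, 7), freqs = freqs) > 0))
  expect_true(all(band_power(m5, c(12, 22), freqs = freqs) == 0))
  expect_error(band_power(map, c(200, 300), freqs = freqs),
               class = "stnlfp_band_error")
})

test_that("dB and z normalization have their closed forms", {
  base <- rep(2, 380)
  expect_equal(db_normalize(2, base), 0)
  expect_equal(db_normalize(20, base), 10)
  expect_equal(db_normalize(1, base), -3.0103, tolerance = 1e-4)
  expect_error(db_normalize(1, rep(0, 10)), class = "stnlfp_numeric_error")

  expect_equal(zscore_epoch(rep(5, 10), c(4, 5, 6, 5, 4, 6)),
               rep(0, 10))
  # affine rescaling of power and baseline leaves z unchanged
  set.seed(5)
  p <- runif(380); b <- runif(380)
  expect_equal(zscore_epoch(3 * p + 1, 3 * b + 1), zscore_epoch(p, b))
  expect_error(zscore_epoch(1:10, rep(1, 10)), class = "stnlfp_numeric_error")

  # sampling oracle: N(0,1) baseline, constant power 2 gives z ~ 2
  set.seed(6)
  z <- zscore_epoch(rep(2, 5), rnorm(20000))
  expect_lt(max(abs(z - 2)), 0.05)
})

test_that("trial QC includes real effects, excludes null and degenerate trials", {
  expect_false(qc_trial(rep(1, 380), rep(1, 380))$included)  # zero difference
  expect_equal(qc_trial(rep(1, 380), rep(1, 380))$reason, "zero_variance")
  set.seed(7)
  b <- runif(380)
  expect_true(qc_trial(b + 10, b + rnorm(380, sd = 1e-3))$included)
  expect_error(qc_trial(rnorm(10), rnorm(12)), class = "stnlfp_config_error")

  # under a null generator, inclusion rate ~ alpha
  set.seed(8)
  inc <- vapply(1:2000, function(i) {
    qc_trial(rnorm(380), rnorm(380))$included
  }, logical(1))
  expect_gt(mean(inc), 0.035)
  expect_lt(mean(inc), 0.065)
})

test_that("time binning partitions the window into four equal means", {
  expect_equal(unname(bin_power(rep(3.5, 380))), rep(3.5, 4))
  ramp <- seq(0, 1, length.out = 380)
  expect_equal(unname(bin_power(ramp)), c(0.125, 0.375, 0.625, 0.875),
               tolerance = 0.005)
  set.seed(9)
  x <- rnorm(380)
  expect_equal(unname(bin_power(x)),
               c(mean(x[1:95]), mean(x[96:190]), mean(x[191:285]),
                 mean(x[286:380])))
  expect_error(bin_power(rnorm(381)), class = "stnlfp_config_error")
})

test_that("epoch extraction is response-locked with correct windows", {
  fs <- 1000
  series <- seq_len(15000) / fs   # value encodes time in s
  trials <- tibble::tibble(
    trial_id = 1:3, block = 1L, depth = "dorsal",
    stim_onset_s = c(9.4, 3.0, 0.05),
    stim_side = "left", correct_side = "left", response_side = "left",
    rt_ms = c(600, 500, 50), correspondence = "Cs",
    accuracy = c("correct", "error", "correct"), iti_prev_ms = 1000
  )
  out <- extract_epochs(series, trials, tf_config(freqs = 2:30), fs = fs)
  # trial 1: response at 10.000 s, analysis covers [9.620, 10.000) s
  expect_equal(nrow(out$epochs), 1)
  ep <- out$epochs$epoch[[1]]
  expect_equal(length(ep), 380)
  expect_equal(ep[1], 9.621, tolerance = 1e-9)     # sample at index of -380 ms
  expect_equal(ep[380], 10.000, tolerance = 1e-9)  # last sample before response
  # intertrial baseline: 380 ms ending 100 ms before stimulus onset
  bl <- out$epochs$baseline[[1]]
  expect_equal(length(bl), 380)
  expect_equal(bl[380], 9.300, tolerance = 1e-9)
  # the error trial emits no epoch; the near-start trial is dropped for bounds
  expect_setequal(out$dropped$reason, c("not_correct", "out_of_bounds"))

  # literal pre-response policy shifts the baseline window
  out2 <- extract_epochs(series, trials,
                         tf_config(freqs = 2:30,
                                   baseline_policy = "literal_preresponse"),
                         fs = fs)
  bl2 <- out2$epochs$baseline[[1]]
  expect_equal(bl2[1], 9.521, tolerance = 1e-9)    # 480 ms before response
  expect_equal(bl2[380], 9.900, tolerance = 1e-9)  # 100 ms before response
})
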