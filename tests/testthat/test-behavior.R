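toy_trials <- function(rt, accuracy = "correct", correspondence = "Cs",
                       depth = "dorsal", subject_id = "s01") {
  n <- length(rt)
  tibble::tibble(
    subject_id = subject_id, trial_id = seq_len(n), block = 1L, depth = depth,
    stim_onset_s = seq_len(n), stim_side = "left",
    correct_side = ifelse(correspondence == "Cs", "left", "right"),
    response_side = "left", rt_ms = rt,
    correspondence = correspondence, accuracy = accuracy, iti_prev_ms = 1000
  )
}

test_that("RT trimming applies the 150 ms and mean + 3 SD rules once", {
  t1 <- toy_trials(c(120, 400, 450))
  expect_equal(trim_rts(t1)$rt_ms, c(400, 450))

  # 50 trials at 400 ms plus one at 5000: only the 5000 exceeds mean + 3 SD
  rts <- c(rep(400, 50), 5000)
  thr <- mean(rts) + 3 * sd(rts)   # independent recomputation: ~2325 ms
  expect_gt(5000, thr)
  expect_equal(trim_rts(toy_trials(rts))$rt_ms, rep(400, 50))

  # equal RTs: SD = 0, threshold = mean, exclusive > removes nothing
  expect_equal(nrow(trim_rts(toy_trials(rep(500, 20)))), 20)

  # never removes a trial with 150 <= rt <= mean + 3 SD (property)
  set.seed(10)
  for (i in 1:20) {
    rts <- round(runif(40, 100, 1200))
    kept <- trim_rts(toy_trials(rts))$rt_ms
    r150 <- rts[rts >= 150]
    safe <- r150[r150 <= mean(r150) + 3 * sd(r150)]
    expect_true(all(safe %in% kept))
  }
})

test_that("condition summaries compute mean RT and accuracy per cell", {
  tr <- dplyr::bind_rows(
    toy_trials(c(500, 600), correspondence = "Cs"),
    toy_trials(c(540, 660), correspondence = "NC")
  )
  s <- condition_summary(tr)
  expect_equal(s$mean_rt_ms[s$correspondence == "Cs"], 550)
  expect_equal(s$mean_rt_ms[s$correspondence == "NC"], 600)
  expect_equal(s$mean_rt_ms[s$correspondence == "NC"] -
                 s$mean_rt_ms[s$correspondence == "Cs"], 50)

  tr2 <- dplyr::bind_rows(
    toy_trials(rep(500, 10), accuracy = c(rep("correct", 9), "error"),
               correspondence = "Cs"),
    toy_trials(rep(500, 10), accuracy = c(rep("correct", 8), "error", "error"),
               correspondence = "NC")
  )
  s2 <- condition_summary(tr2)
  expect_equal(s2$accuracy_pct[s2$correspondence == "Cs"], 90)
  expect_equal(s2$accuracy_pct[s2$correspondence == "NC"], 80)
})

test_that("rank binning is stable with the remainder rule", {
  expect_equal(table(quantile_bins(sample(8))) |> as.integer(), rep(2L, 4))
  expect_equal(table(quantile_bins(sample(10))) |> as.integer(),
               c(3L, 3L, 2L, 2L))
  # ties keep input order: earlier-input tied trial goes to the earlier bin
  b <- quantile_bins(c(300, 300, 300, 300, 300, 300, 300, 300))
  expect_equal(b, c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_error(quantile_bins(c(1, 2, 3)), class = "stnlfp_binning_error")
  # bins are contiguous in rank and sizes sum to n
  set.seed(11)
  rts <- runif(23, 300, 900)
  bins <- quantile_bins(rts)
  expect_equal(length(bins), 23)
  expect_true(all(diff(bins[order(rts)]) >= 0))
})

test_that("delta plot follows the stated arithmetic (toy slope -0.5)", {
  # construct trials whose bin means are exactly the toy example
  cs_rts <- rep(c(400, 450, 500, 600), each = 4)
  nc_rts <- rep(c(450, 510, 560, 620), each = 4)
  tr <- dplyr::bind_rows(toy_trials(cs_rts, correspondence = "Cs"),
                         toy_trials(nc_rts, correspondence = "NC"))
  d <- delta_plot(tr)
  expect_equal(d$interference, c(50, 60, 60, 20))
  expect_equal(d$mean_rt, c(425, 480, 530, 610))
  slope <- final_delta_slope(d)$final_delta_slope
  expect_equal(slope, (20 - 60) / (610 - 530))
  expect_equal(slope, -0.5)

  # identical distributions: zero interference everywhere, slope 0
  tr0 <- dplyr::bind_rows(toy_trials(cs_rts, correspondence = "Cs"),
                          toy_trials(cs_rts, correspondence = "NC"))
  d0 <- delta_plot(tr0)
  expect_true(all(d0$interference == 0))
  expect_equal(final_delta_slope(d0)$final_delta_slope, 0)

  # antisymmetry under swapping the Cs/NC labels
  tr_sw <- dplyr::bind_rows(toy_trials(nc_rts, correspondence = "Cs"),
                            toy_trials(cs_rts, correspondence = "NC"))
  d_sw <- delta_plot(tr_sw)
  expect_equal(d_sw$interference, -d$interference)
  expect_equal(final_delta_slope(d_sw)$final_delta_slope, -slope)
})

test_that("late suppression produces a negative final delta slope", {
  hits <- vapply(1:20, function(i) {
    cfg <- sim_config(trials_per_block = 180, blocks_per_depth = 4,
                      late_suppression = 1, simon_rt_shift_ms = 80,
                      p_impulse_error = 0, seed = 8000 + i)
    tr <- trim_rts(simulate_behavior(cfg))
    mean(final_delta_slope(delta_plot(tr))$final_delta_slope) < 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("conditional accuracy is computed per bin on responded trials", {
  tr <- toy_trials(rep(c(300, 400, 500, 600), each = 10),
                   accuracy = c(rep("error", 3), rep("correct", 37)),
                   correspondence = "NC")
  caf <- conditional_accuracy(tr)
  expect_equal(caf$accuracy_pct[caf$bin == 1], 70)
  expect_true(all(caf$accuracy_pct[caf$bin > 1] == 100))

  # error-free table: 100% everywhere
  caf0 <- conditional_accuracy(toy_trials(runif(40, 300, 900)))
  expect_true(all(caf0$accuracy_pct == 100))
})

test_that("paired t-test matches the textbook formula", {
  expect_equal(paired_t(rep(1, 5), rep(1, 5)),
               tibble::tibble(n = 5L, mean_diff = 0, t = 0, df = 4L, p = 1,
                              cohens_d = 0),
               ignore_attr = TRUE)
  expect_error(paired_t(c(2, 2, 2, 2), c(1, 1, 1, 1)),
               class = "stnlfp_degenerate_error")

  set.seed(12)
  a <- rnorm(10, 1); b <- rnorm(10)
  out <- paired_t(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(10))          # textbook paired t
  p_hand <- 2 * pt(-abs(t_hand), df = 9)
  expect_equal(out$t, t_hand)
  expect_equal(out$p, p_hand)
  expect_equal(out$cohens_d, mean(d) / sd(d))
})

test_that("behavior summary assembles effects on subject-level means", {
  cfg <- sim_config(n_subjects = 6, trials_per_block = 120,
                    blocks_per_depth = 2, seed = 61)
  co <- simulate_cohort(cfg, signals = FALSE)
  bs <- behavior_summary(co$trials)
  expect_s3_class(bs, "stn_behavior_summary")
  expect_equal(nrow(bs$cells), 4)
  # a positive Simon RT cost is generated at both depths
  expect_true(all(bs$effects$simon_rt_ms > 0))
  # effects equal the difference of the per-depth cell means
  for (dep in c("dorsal", "ventral")) {
    cells <- bs$cells[bs$cells$depth == dep, ]
    expect_equal(
      bs$effects$simon_rt_ms[bs$effects$depth == dep],
      cells$mean_rt_ms[cells$correspondence == "NC"] -
        cells$mean_rt_ms[cells$correspondence == "Cs"]
    )
  }
})
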