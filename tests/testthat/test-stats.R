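test_that("log transform has its closed forms and guards the ratio scale", {
  out <- log_transform(c(1, exp(1), 2))
  expect_equal(as.numeric(out), c(0, 1, 0.6931), tolerance = 1e-4)
  expect_equal(attr(out, "n_dropped"), 0)
  withNA <- log_transform(c(1, -0.5, rep(2, 48)))
  expect_true(is.na(withNA[2]))
  expect_equal(attr(withNA, "n_dropped"), 1)
  expect_error(log_transform(c(-1, -2, 3)), class = "stnlfp_numeric_error")
})

test_that("mixed model recovers cell means and steps down its ladder", {
  pc <- simulate_powercells(sim_config(seed = 71))
  fit <- fit_mixed(dplyr::filter(pc, .data$band == "theta"))
  expect_s3_class(fit, "stn_lfp_fit")
  expect_true(fit$ladder_step %in% c("full", "no_time", "intercept"))

  # on balanced complete data, estimated marginal means equal raw cell means
  d <- fit$data
  raw <- d |>
    dplyr::group_by(.data$subregion, .data$correspondence,
                    .data$hemisphere_rel) |>
    dplyr::summarise(m = mean(.data$.y), .groups = "drop")
  emm <- tidy(fit, "cells")
  j <- dplyr::inner_join(raw, emm,
                         by = c("subregion", "correspondence",
                                "hemisphere_rel"))
  expect_equal(j$estimate, j$m, tolerance = 1e-6)

  # tidy/glance expose the F table and fit metadata
  tf <- tidy(fit)
  expect_setequal(
    tf$term,
    c("subregion", "correspondence", "hemisphere_rel",
      "subregion:correspondence", "correspondence:hemisphere_rel",
      "subregion:correspondence:hemisphere_rel"))
  expect_equal(tidy(fit)$df_num[6], 2)   # three-way carries 2 df
  g <- glance(fit)
  expect_equal(g$nobs, nrow(d))
  expect_error(fit_mixed(dplyr::filter(pc, .data$subject_id == "s01")),
               class = "stnlfp_model_error")
})

test_that("cell contrasts equal cell-mean differences and ignore coding", {
  pc <- simulate_powercells(sim_config(seed = 72))
  th <- dplyr::filter(pc, .data$band == "theta")
  fit <- fit_mixed(th)
  # self-contrast is exactly null
  self <- cell_contrast(fit, list(subregion = "dorsal"),
                        list(subregion = "dorsal"))
  expect_equal(self$estimate, 0)
  expect_equal(self$p, 1)

  # balanced data: contrast equals difference of raw cell means
  raw <- th |>
    dplyr::group_by(.data$subregion, .data$correspondence) |>
    dplyr::summarise(m = mean(.data$log_power), .groups = "drop")
  ct <- cell_contrast(fit, list(subregion = "dorsal", correspondence = "NC"),
                      list(subregion = "dorsal", correspondence = "Cs"))
  expect_equal(
    ct$estimate,
    raw$m[raw$subregion == "dorsal" & raw$correspondence == "NC"] -
      raw$m[raw$subregion == "dorsal" & raw$correspondence == "Cs"],
    tolerance = 1e-6
  )

  # invariance to reference-level recoding of the factors
  th2 <- th |>
    dplyr::mutate(subregion = factor(.data$subregion,
                                     levels = c("ventral", "dorsal")),
                  correspondence = factor(.data$correspondence,
                                          levels = c("NC", "Cs")))
  fit2 <- fit_mixed(th2)
  ct2 <- cell_contrast(fit2, list(subregion = "dorsal", correspondence = "NC"),
                       list(subregion = "dorsal", correspondence = "Cs"))
  expect_equal(ct2$estimate, ct$estimate, tolerance = 1e-6)
  expect_equal(ct2$p, ct$p, tolerance = 1e-4)

  expect_error(cell_contrast(fit, list(subregion = "medial"),
                             list(subregion = "dorsal")),
               class = "stnlfp_model_error")
})

test_that("a constant response yields null fixed effects", {
  pc <- simulate_powercells(sim_config(seed = 73)) |>
    dplyr::filter(.data$band == "theta") |>
    dplyr::mutate(log_power = 0.7)
  fit <- fit_mixed(pc)
  expect_equal(fit$ladder_step, "intercept")
  fx <- lme4::fixef(fit$model)
  expect_lt(max(abs(fx[-1])), 1e-8)
  expect_equal(unname(fx[1]), 0.7, tolerance = 1e-8)
})

test_that("Spearman correlation handles monotone, reversed and degenerate input", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(baseline_behavior_correlation(x, x^3)$rho, 1)
  expect_equal(baseline_behavior_correlation(x, -x)$rho, -1)
  expect_error(baseline_behavior_correlation(rep(1, 5), x),
               class = "stnlfp_degenerate_error")
  expect_error(baseline_behavior_correlation(c(1, 2), c(2, 1)),
               class = "stnlfp_config_error")
})
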