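#' Trim reaction times
#'
#' Removes anticipatory responses (RT < 150 ms) and then, within each
#' subject x depth x correspondence cell, responses slower than the cell
#' mean + 3 SD computed on the post-150 ms set. A single pass: the 3 SD
#' threshold is not re-iterated after removal. Non-responded rows
#' (omissions, too-early) are untouched.
#'
#' @param trials A trial table.
#' @return The table with trimmed rows removed. Cells left empty by trimming
#'   raise a warning and are flagged in the `"empty_cells"` attribute.
#' @export
trim_rts <- function(trials) {
  trials <- tibble::as_tibble(trials)
  responded <- !is.na(trials$rt_ms)
  keep_fast <- !(responded & trials$rt_ms < 150)
  kept <- trials[keep_fast, , drop = FALSE]
  grp_vars <- intersect(c("subject_id", "depth", "correspondence"), names(kept))
  kept <- kept |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_vars))) |>
    dplyr::mutate(
      .thr = mean(.data$rt_ms[!is.na(.data$rt_ms)]) +
        3 * sd(.data$rt_ms[!is.na(.data$rt_ms)]),
      .thr = ifelse(is.na(.thr), Inf, .thr)   # single RT in cell: sd undefined
    ) |>
    dplyr::ungroup()
  slow <- !is.na(kept$rt_ms) & kept$rt_ms > kept$.thr
  out <- kept[!slow, setdiff(names(kept), ".thr"), drop = FALSE]
  empty <- dplyr::anti_join(
    dplyr::distinct(trials[responded, grp_vars, drop = FALSE]),
    dplyr::distinct(out[!is.na(out$rt_ms), grp_vars, drop = FALSE]),
    by = grp_vars
  )
  if (nrow(empty) > 0) {
    warn("some subject x depth x correspondence cells are empty after RT trimming.",
         class = "stnlfp_empty_cell_warning")
  }
  attr(out, "empty_cells") <- empty
  out
}

#' Per-condition behavioral summary cells
#'
#' Mean correct-trial RT and percent-correct accuracy per subject x depth x
#' correspondence. Accuracy counts errors against responded trials only
#' (omissions and too-early trials are excluded from the denominator).
#'
#' @param trials A (trimmed) trial table.
#' @return Tibble with `subject_id` (if present), `depth`, `correspondence`,
#'   `n_responded`, `mean_rt_ms`, `accuracy_pct`.
#' @export
condition_summary <- function(trials) {
  grp_vars <- intersect(c("subject_id", "depth", "correspondence"),
                        names(trials))
  trials |>
    dplyr::filter(.data$accuracy %in% c("correct", "error")) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_vars))) |>
    dplyr::summarise(
      n_responded = dplyr::n(),
      mean_rt_ms = mean(.data$rt_ms[.data$accuracy == "correct"]),
      accuracy_pct = 100 * mean(.data$accuracy == "correct"),
      .groups = "drop"
    )
}

#' Rank-order RTs into equal-sized bins
#'
#' Stable sort from fastest to slowest, then contiguous bins; when the trial
#' count is not divisible by `n_bins`, the remainder `r` gives one extra
#' trial to each of the first `r` (fastest) bins. Ties keep input order, so
#' the earlier-input trial goes to the earlier bin.
#'
#' @param rts Numeric reaction times.
#' @param n_bins Number of bins.
#' @return Integer bin assignment in the input order of `rts`.
#' @export
#' @examples
#' quantile_bins(10:1)  # bin sizes 3, 3, 2, 2 from fastest to slowest
quantile_bins <- function(rts, n_bins = 4) {
  n <- length(rts)
  if (n < n_bins) {
    stn_error(sprintf("need at least %d trials to form %d bins.", n_bins,
                      n_bins),
              "stnlfp_binning_error")
  }
  base <- n %/% n_bins
  rem <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
  bins_sorted <- rep(seq_len(n_bins), times = sizes)
  ord <- order(rts)               # stable: ties keep input order
  out <- integer(n)
  out[ord] <- bins_sorted
  out
}

#' Delta plot of the Simon RT interference across the RT distribution
#'
#' Within each subject x depth, correct trimmed trials are rank-binned
#' separately for Cs and NC; per bin `b` the interference is
#' `d_b = meanRT_NC,b - meanRT_Cs,b`, plotted against
#' `x_b = (meanRT_NC,b + meanRT_Cs,b) / 2`.
#'
#' @param trials A trimmed trial table.
#' @param n_bins Number of RT bins.
#' @return A tibble of class `stn_delta_plot`: one row per subject x depth x
#'   bin with `rt_cs`, `rt_nc`, `mean_rt`, `interference`.
#' @seealso [final_delta_slope()] for the last-segment suppression slope.
#' @export
delta_plot <- function(trials, n_bins = 4) {
  grp_vars <- intersect(c("subject_id", "depth"), names(trials))
  out <- trials |>
    dplyr::filter(.data$accuracy == "correct") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp_vars, "correspondence")))) |>
    dplyr::mutate(bin = quantile_bins(.data$rt_ms, n_bins)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp_vars, "correspondence",
                                                  "bin")))) |>
    dplyr::summarise(mean_rt_ms = mean(.data$rt_ms), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "correspondence",
                       values_from = "mean_rt_ms") |>
    dplyr::mutate(
      rt_cs = .data$Cs, rt_nc = .data$NC,
      mean_rt = (.data$Cs + .data$NC) / 2,
      interference = .data$NC - .data$Cs,
      .keep = "unused"
    )
  class(out) <- c("stn_delta_plot", class(out))
  out
}

#' Final suppression slope of the delta plot
#'
#' The slope of the delta plot between its last two bins,
#' `(d_n - d_{n-1}) / (x_n - x_{n-1})` (dimensionless: change in
#' interference ms per change in mean RT ms). Negative-going slopes index
#' more proficient selective suppression of the location-driven impulse.
#'
#' @param delta A tibble from [delta_plot()].
#' @return Tibble per subject x depth with `final_delta_slope`.
#' @export
final_delta_slope <- function(delta) {
  grp_vars <- intersect(c("subject_id", "depth"), names(delta))
  delta |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_vars))) |>
    dplyr::arrange(.data$bin, .by_group = TRUE) |>
    dplyr::summarise(
      final_delta_slope = {
        nb <- dplyr::n()
        dx <- .data$mean_rt[nb] - .data$mean_rt[nb - 1]
        if (dx == 0) {
          warn("undefined final delta slope: equal mean RT in last two bins.",
               class = "stnlfp_slope_warning")
          NA_real_
        } else {
          (.data$interference[nb] - .data$interference[nb - 1]) / dx
        }
      },
      .groups = "drop"
    )
}

#' Conditional accuracy function
#'
#' Percent correct per RT bin, binned over all responded trials (errors
#' included) separately within each correspondence condition. Depressed
#' accuracy in the fastest NC bin indexes the strength of impulse capture.
#'
#' @param trials A trimmed trial table.
#' @param n_bins Number of RT bins.
#' @return A tibble of class `stn_caf`: per subject x depth x correspondence
#'   x bin with `n` and `accuracy_pct`.
#' @export
conditional_accuracy <- function(trials, n_bins = 4) {
  grp_vars <- intersect(c("subject_id", "depth"), names(trials))
  out <- trials |>
    dplyr::filter(.data$accuracy %in% c("correct", "error")) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp_vars, "correspondence")))) |>
    dplyr::mutate(bin = quantile_bins(.data$rt_ms, n_bins)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp_vars, "correspondence",
                                                  "bin")))) |>
    dplyr::summarise(n = dplyr::n(),
                     accuracy_pct = 100 * mean(.data$accuracy == "correct"),
                     .groups = "drop")
  class(out) <- c("stn_caf", class(out))
  out
}

#' Paired t-test with Cohen's d
#'
#' Two-sided paired t-test on subject-level vectors, with
#' `d = mean(diff) / sd(diff)`.
#'
#' @param values_a,values_b Equal-length paired subject-level vectors,
#'   n >= 2.
#' @return A one-row tibble: `n`, `mean_diff`, `t`, `df`, `p`, `cohens_d`.
#' @export
paired_t <- function(values_a, values_b) {
  if (length(values_a) != length(values_b) || length(values_a) < 2) {
    stn_error("paired_t needs two equal-length vectors with n >= 2.",
              "stnlfp_config_error")
  }
  d <- values_a - values_b
  if (all(d == 0)) {
    return(tibble::tibble(n = length(d), mean_diff = 0, t = 0,
                          df = length(d) - 1, p = 1, cohens_d = 0))
  }
  if (sd(d) == 0) {
    stn_error("paired differences have zero variance; t is undefined.",
              "stnlfp_degenerate_error")
  }
  tt <- t.test(values_a, values_b, paired = TRUE)
  tibble::tibble(
    n = length(d), mean_diff = mean(d), t = unname(tt$statistic),
    df = unname(tt$parameter), p = unname(tt$p.value),
    cohens_d = mean(d) / sd(d)
  )
}

#' Group-level behavioral summary (report-table schema)
#'
#' Assembles the behavioral battery at the group level: per depth x
#' correspondence mean RT and accuracy (subject-level means first, then
#' averaged across subjects, with SEs), the Simon effects (NC - Cs RT cost,
#' Cs - NC accuracy cost) with paired t-tests and Cohen's d, final delta
#' slopes, and fastest-bin NC accuracy.
#'
#' @param trials An untrimmed trial table (trimming is applied internally).
#' @param n_bins RT bins for the distributional measures.
#' @return A list of class `stn_behavior_summary`: `cells` (per depth x
#'   condition means and SEs), `effects` (per depth Simon RT and accuracy
#'   effects with tests), `distribution` (final delta slope and NC fastest-
#'   bin accuracy per depth, with the dorsal-ventral comparisons),
#'   `by_subject` (the subject-level cells), `delta` and `caf` tibbles.
#' @export
behavior_summary <- function(trials, n_bins = 4) {
  trimmed <- trim_rts(trials)
  by_subject <- condition_summary(trimmed)
  se <- function(x) sd(x) / sqrt(sum(!is.na(x)))

  cells <- by_subject |>
    dplyr::group_by(.data$depth, .data$correspondence) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      se_rt_ms = se(.data$mean_rt_ms),
      mean_rt_ms = mean(.data$mean_rt_ms),
      se_acc = se(.data$accuracy_pct),
      accuracy_pct = mean(.data$accuracy_pct),
      .groups = "drop"
    )

  wide <- by_subject |>
    tidyr::pivot_wider(names_from = "correspondence",
                       values_from = c("mean_rt_ms", "accuracy_pct"),
                       id_cols = c("subject_id", "depth"))
  effects <- wide |>
    dplyr::group_by(.data$depth) |>
    dplyr::group_modify(function(d, key) {
      tt_rt <- paired_t(d$mean_rt_ms_NC, d$mean_rt_ms_Cs)
      tt_acc <- paired_t(d$accuracy_pct_Cs, d$accuracy_pct_NC)
      tibble::tibble(
        simon_rt_ms = tt_rt$mean_diff, rt_t = tt_rt$t, rt_df = tt_rt$df,
        rt_p = tt_rt$p, rt_d = tt_rt$cohens_d,
        simon_acc_pct = tt_acc$mean_diff, acc_t = tt_acc$t,
        acc_df = tt_acc$df, acc_p = tt_acc$p, acc_d = tt_acc$cohens_d
      )
    }) |>
    dplyr::ungroup()

  delta <- delta_plot(trimmed, n_bins)
  slopes <- final_delta_slope(delta)
  caf <- conditional_accuracy(trimmed, n_bins)
  nc_bin1 <- caf |>
    dplyr::filter(.data$correspondence == "NC", .data$bin == 1) |>
    dplyr::select(dplyr::any_of(c("subject_id", "depth")),
                  nc_acc_bin1_pct = "accuracy_pct")

  distribution <- dplyr::full_join(
    slopes |>
      dplyr::group_by(.data$depth) |>
      dplyr::summarise(se_slope = se(.data$final_delta_slope),
                       final_delta_slope = mean(.data$final_delta_slope),
                       .groups = "drop"),
    nc_bin1 |>
      dplyr::group_by(.data$depth) |>
      dplyr::summarise(se_nc_acc_bin1 = se(.data$nc_acc_bin1_pct),
                       nc_acc_bin1_pct = mean(.data$nc_acc_bin1_pct),
                       .groups = "drop"),
    by = "depth"
  )

  comparisons <- list()
  slope_wide <- tidyr::pivot_wider(slopes, names_from = "depth",
                                   values_from = "final_delta_slope")
  bin1_wide <- tidyr::pivot_wider(nc_bin1, names_from = "depth",
                                  values_from = "nc_acc_bin1_pct")
  if (all(c("dorsal", "ventral") %in% names(slope_wide))) {
    cc <- stats::complete.cases(slope_wide[c("dorsal", "ventral")])
    if (sum(cc) >= 2) {
      comparisons$slope_dorsal_vs_ventral <-
        paired_t(slope_wide$dorsal[cc], slope_wide$ventral[cc])
    }
    cc <- stats::complete.cases(bin1_wide[c("dorsal", "ventral")])
    if (sum(cc) >= 2) {
      comparisons$nc_acc_bin1_dorsal_vs_ventral <-
        paired_t(bin1_wide$dorsal[cc], bin1_wide$ventral[cc])
    }
  }

  structure(
    list(cells = cells, effects = effects, distribution = distribution,
         comparisons = comparisons, by_subject = by_subject, delta = delta,
         caf = caf),
    class = "stn_behavior_summary"
  )
}

#' @export
print.stn_behavior_summary <- function(x, ...) {
  cat("<stn_behavior_summary>\n\nCondition cells:\n")
  print(x$cells)
  cat("\nSimon effects:\n")
  print(x$effects)
  cat("\nDistributional measures:\n")
  print(x$distribution)
  invisible(x)
}
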