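#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_raster facet_wrap labs scale_fill_viridis_c stat_summary
#' @export
ggplot2::autoplot

#' Plot a delta plot (RT interference across the RT distribution)
#'
#' Interference (NC - Cs mean RT per rank bin) against bin mean RT, one
#' line per depth, averaged across subjects.
#'
#' @param object An `stn_delta_plot` from [delta_plot()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stn_delta_plot
#' @export
autoplot.stn_delta_plot <- function(object, ...) {
  d <- object |>
    dplyr::group_by(.data$depth, .data$bin) |>
    dplyr::summarise(mean_rt = mean(.data$mean_rt),
                     interference = mean(.data$interference),
                     .groups = "drop")
  ggplot(d, aes(x = .data$mean_rt, y = .data$interference,
                colour = .data$depth)) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    geom_line() + geom_point() +
    labs(x = "bin mean RT (ms)", y = "interference NC - Cs (ms)",
         colour = "STN depth", title = "Delta plot")
}

#' Plot a conditional accuracy function
#'
#' Percent correct per RT bin for Cs and NC trials, faceted by depth,
#' averaged across subjects. Depressed accuracy in the fastest NC bin
#' indexes impulse capture.
#'
#' @param object An `stn_caf` from [conditional_accuracy()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot stn_caf
#' @export
autoplot.stn_caf <- function(object, ...) {
  d <- object |>
    dplyr::group_by(.data$depth, .data$correspondence, .data$bin) |>
    dplyr::summarise(accuracy_pct = mean(.data$accuracy_pct),
                     .groups = "drop")
  ggplot(d, aes(x = .data$bin, y = .data$accuracy_pct,
                colour = .data$correspondence)) +
    geom_line() + geom_point() +
    facet_wrap(~ .data$depth) +
    labs(x = "RT bin (fast to slow)", y = "accuracy (% correct)",
         colour = NULL, title = "Conditional accuracy function")
}

#' Plot a time-frequency power map
#'
#' @param object An `stn_tfr` from [morlet_power()].
#' @param ... Unused.
#' @return A ggplot (time on x, frequency on y, power as fill).
#' @method autoplot stn_tfr
#' @export
autoplot.stn_tfr <- function(object, ...) {
  d <- tidyr::expand_grid(t = seq_len(ncol(object$power)) / object$fs,
                          freq = object$freqs)
  d$power <- as.vector(object$power)   # column-major: frequency varies fastest
  ggplot(d, aes(x = .data$t, y = .data$freq, fill = .data$power)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "time (s)", y = "frequency (Hz)", fill = "power")
}

#' Plot normalized band power by condition across the pre-response window
#'
#' Cell-mean z-scored band power across the four pre-response time bins,
#' split by correspondence, faceted by subregion and relative hemisphere.
#'
#' @param powercells The `powercells` tibble from [compute_powercells()].
#' @param band `"theta"` or `"beta"`.
#' @return A ggplot.
#' @export
plot_power_bins <- function(powercells, band = c("theta", "beta")) {
  band <- match.arg(band)
  d <- powercells |>
    dplyr::filter(.data$band == !!band) |>
    dplyr::group_by(.data$subregion, .data$hemisphere_rel,
                    .data$correspondence, .data$time_bin) |>
    dplyr::summarise(mean_z = mean(.data$mean_z), .groups = "drop") |>
    dplyr::mutate(time_ms = -380 + 95 * (.data$time_bin - 0.5))
  ggplot(d, aes(x = .data$time_ms, y = .data$mean_z,
                colour = .data$correspondence)) +
    geom_line() + geom_point() +
    facet_wrap(~ .data$subregion + .data$hemisphere_rel) +
    labs(x = "time before response (ms)", y = "z-scored band power",
         colour = NULL, title = paste(band, "band"))
}
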