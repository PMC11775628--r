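#' Reference results tables
#'
#' The published summary tables of the intraoperative STN Simon-task study
#' whose analysis this package reimplements, shipped as plain CSV: the
#' behavioral condition table, per-band cell means of log-transformed power
#' (subregion x relative hemisphere x correspondence) with standard errors,
#' the distributional behavioral measures, the baseline-power/behavior
#' Spearman correlations, and the marginal means the study reports in its
#' results text. They define the report schemas the pipeline mirrors and
#' support arithmetic cross-checks of the reported marginals against their
#' table cells (see [crossfoot_marginals()]).
#'
#' @return A named list of tibbles: `behavior`, `theta_cells`, `beta_cells`,
#'   `distribution`, `correlations`, `reported_marginals`.
#' @export
reference_tables <- function() {
  rd <- function(name) {
    readr::read_csv(system.file("extdata", name, package = "stnlfp",
                                mustWork = TRUE),
                    show_col_types = FALSE, progress = FALSE)
  }
  list(
    behavior = rd("ref_behavior.csv"),
    theta_cells = rd("ref_theta_cells.csv"),
    beta_cells = rd("ref_beta_cells.csv"),
    distribution = rd("ref_distribution.csv"),
    correlations = rd("ref_correlations.csv"),
    reported_marginals = rd("ref_reported_marginals.csv")
  )
}

#' @noRd
scope_filter <- function(cells, scope) {
  for (part in strsplit(scope, "_", fixed = TRUE)[[1]]) {
    col <- if (part %in% SUBREGIONS) "subregion"
      else if (part %in% CORRESPONDENCE) "correspondence"
      else if (part %in% HEMI_REL) "hemisphere_rel"
      else stn_error(sprintf("unknown marginal scope part '%s'.", part),
                     "stnlfp_config_error")
    cells <- cells[cells[[col]] == part, , drop = FALSE]
  }
  cells
}

#' Cross-foot reported marginal means against their table cells
#'
#' For each marginal mean reported in the study's results text (e.g. the
#' dorsal theta mean across correspondence and hemispheres), computes the
#' unweighted average of the corresponding cells of the per-band cell-mean
#' table and pairs it with the reported value. Agreement to the printed
#' precision (two decimals) verifies that the reported marginals are
#' unweighted cell averages.
#'
#' @param ref Output of [reference_tables()] (computed if omitted).
#' @return A tibble: `band`, `scope`, `reported`, `computed`, `abs_diff`.
#' @export
#' @examples
#' crossfoot_marginals()
crossfoot_marginals <- function(ref = reference_tables()) {
  purrr::pmap(ref$reported_marginals, function(band, scope, mean_log_power) {
    cells <- if (band == "theta") ref$theta_cells else ref$beta_cells
    computed <- mean(scope_filter(cells, scope)$mean_log_power)
    tibble::tibble(band = band, scope = scope, reported = mean_log_power,
                   computed = computed,
                   abs_diff = abs(computed - mean_log_power))
  }) |>
    dplyr::bind_rows()
}
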