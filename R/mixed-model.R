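#' Log-transform baseline-ratio power
#'
#' Natural log of normalized band power on the baseline-ratio scale
#' (analysis-window power divided by the trial's baseline mean). Values
#' that are not strictly positive on the ratio scale cannot be logged; they
#' are returned as `NA` with their count in the `"n_dropped"` attribute.
#' More than 5% non-positive values aborts, since that indicates a
#' normalization problem upstream rather than a few degenerate trials.
#'
#' @param values Ratio-scale power values.
#' @return The log-transformed vector (`NA` where non-positive), with
#'   attribute `n_dropped`.
#' @export
#' @examples
#' log_transform(c(1, exp(1), 2))  # 0, 1, 0.6931
log_transform <- function(values) {
  bad <- !is.na(values) & values <= 0
  if (mean(bad) > 0.05) {
    stn_error(sprintf(
      "%.1f%% of power ratios are non-positive; review the normalization configuration.",
      100 * mean(bad)),
      "stnlfp_numeric_error")
  }
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values) & values > 0
  out[ok] <- log(values[ok])
  attr(out, "n_dropped") <- sum(bad)
  out
}

#' @noRd
prepare_model_frame <- function(powercells, response) {
  d <- tibble::as_tibble(powercells)
  needed <- c("subject_id", "subregion", "hemisphere_rel", "correspondence",
              "time_bin", response)
  missing <- setdiff(needed, names(d))
  if (length(missing)) {
    stn_error(paste0("power cells are missing columns: ",
                     paste(missing, collapse = ", ")),
              "stnlfp_schema_error")
  }
  d$subject_id <- factor(d$subject_id)
  d$subregion <- factor(d$subregion, levels = SUBREGIONS)
  d$hemisphere_rel <- factor(d$hemisphere_rel, levels = HEMI_REL)
  d$correspondence <- factor(d$correspondence, levels = CORRESPONDENCE)
  d$.time_c <- d$time_bin - mean(range(d$time_bin))
  d$.corr_nc <- as.numeric(d$correspondence == "NC")
  d$.y <- d[[response]]
  d[!is.na(d$.y), , drop = FALSE]
}

FIXED_RHS <- paste(
  "subregion + correspondence + hemisphere_rel",
  "+ subregion:correspondence + correspondence:hemisphere_rel",
  "+ subregion:correspondence:hemisphere_rel"
)

#' @noRd
ladder_formulas <- function() {
  list(
    full = paste(".y ~", FIXED_RHS,
                 "+ (1 | subject_id) + (0 + .corr_nc | subject_id)",
                 "+ (0 + .time_c | subject_id:subregion:correspondence)"),
    no_time = paste(".y ~", FIXED_RHS,
                    "+ (1 | subject_id) + (0 + .corr_nc | subject_id)"),
    intercept = paste(".y ~", FIXED_RHS, "+ (1 | subject_id)")
  )
}

#' Fit the band-power linear mixed model
#'
#' REML fit of log band power on STN subregion, correspondence and relative
#' hemisphere, with the subregion x correspondence, correspondence x
#' hemisphere and three-way interactions as fixed effects (no subregion x
#' hemisphere two-way, so the three-way carries 2 numerator df), a random
#' intercept per subject, a random slope for correspondence, and a random
#' slope for time bin nested within correspondence within subregion. Time
#' bin enters the random part only. Fixed-term F-tests use Satterthwaite
#' denominator degrees of freedom.
#'
#' When a step of the random structure fails to converge or fits singular,
#' the model steps down a pre-registered ladder: drop the nested time slope,
#' then the correspondence slope, leaving the subject intercept. The step
#' actually used is recorded in the result; a singular fit at the last step
#' is an error.
#'
#' @param powercells Tibble with one row per subject x subregion x relative
#'   hemisphere x correspondence x time bin and a log-power response column.
#' @param spec An [model_spec()].
#' @param response Name of the response column.
#' @return An object of class `stn_lfp_fit`: list with `model` (the
#'   `lmerModLmerTest` fit), `anova` (Satterthwaite type-III F table),
#'   `ladder_step` (`"full"`, `"no_time"` or `"intercept"`), `emmeans`
#'   (estimated marginal means of the 8 design cells on the log scale),
#'   `spec` and `data`.
#' @export
fit_mixed <- function(powercells, spec = model_spec(),
                      response = "log_power") {
  d <- prepare_model_frame(powercells, response)
  if (nlevels(droplevels(d$subject_id)) < 2) {
    stn_error("the mixed model needs at least 2 subjects.",
              "stnlfp_model_error")
  }
  forms <- ladder_formulas()
  start <- match(spec$random, names(forms))
  fit <- NULL
  step_used <- NA_character_
  for (step in names(forms)[start:length(forms)]) {
    fit_try <- suppressMessages(withCallingHandlers(
      tryCatch(
        lmerTest::lmer(stats::as.formula(forms[[step]]), data = d,
                       REML = TRUE),
        error = function(e) NULL
      ),
      warning = function(w) invokeRestart("muffleWarning")
    ))
    if (is.null(fit_try)) next
    converged <- length(fit_try@optinfo$conv$lme4$messages %||% character(0)) == 0
    singular <- lme4::isSingular(fit_try, tol = 1e-4)
    if (converged && !singular) {
      fit <- fit_try
      step_used <- step
      break
    }
    if (step == "intercept") {
      if (var(d$.y) == 0) {
        # degenerate constant response: the fit is necessarily singular but
        # well defined (all fixed effects zero)
        fit <- fit_try
        step_used <- step
        break
      }
      if (!converged) {
        stn_error("mixed model failed to converge at the last ladder step.",
                  "stnlfp_model_error")
      }
      # singular subject intercept at the last step
      stn_error(paste0(
        "singular fit at the last ladder step (subject intercept variance 0); ",
        "theta = ", paste(round(lme4::getME(fit_try, "theta"), 4),
                          collapse = ", ")),
        "stnlfp_model_error")
    }
  }
  an <- suppressMessages(stats::anova(fit))
  emm <- suppressMessages(emmeans::emmeans(
    fit, ~ subregion * correspondence * hemisphere_rel,
    lmer.df = "satterthwaite"
  ))
  structure(
    list(model = fit, anova = an, ladder_step = step_used, emmeans = emm,
         spec = spec, data = d),
    class = "stn_lfp_fit"
  )
}

#' @export
print.stn_lfp_fit <- function(x, ...) {
  cat(sprintf("<stn_lfp_fit> random structure: %s\n\n", x$ladder_step))
  print(x$anova)
  invisible(x)
}

#' @noRd
cell_weights <- function(grid, cell) {
  keep <- rep(TRUE, nrow(grid))
  for (nm in names(cell)) {
    if (!nm %in% names(grid)) {
      stn_error(sprintf("unknown design factor '%s'.", nm),
                "stnlfp_model_error")
    }
    if (!cell[[nm]] %in% grid[[nm]]) {
      stn_error(sprintf("cell level '%s' is absent from the design.",
                        cell[[nm]]),
                "stnlfp_model_error")
    }
    keep <- keep & grid[[nm]] == cell[[nm]]
  }
  if (!any(keep)) {
    stn_error("requested cell is absent from the design.",
              "stnlfp_model_error")
  }
  as.numeric(keep) / sum(keep)
}

#' Linear contrast between design cells
#'
#' Difference of estimated marginal means between two cells of the
#' subregion x correspondence x hemisphere design (or averages over cells:
#' omit a factor to average across it), with standard error from the fixed-
#' effect covariance and a two-sided p-value on Satterthwaite df.
#'
#' @param fit An `stn_lfp_fit` from [fit_mixed()].
#' @param cell_a,cell_b Named lists selecting cells, e.g.
#'   `list(subregion = "dorsal", correspondence = "NC")` (averaged over
#'   hemispheres).
#' @return One-row tibble: `estimate`, `se`, `t`, `df`, `p`.
#' @export
#' @examples
#' \dontrun{
#' cell_contrast(fit, list(subregion = "dorsal", correspondence = "NC"),
#'                    list(subregion = "dorsal", correspondence = "Cs"))
#' }
cell_contrast <- function(fit, cell_a, cell_b) {
  stopifnot(inherits(fit, "stn_lfp_fit"))
  grid <- as.data.frame(fit$emmeans)[c("subregion", "correspondence",
                                       "hemisphere_rel")]
  w <- cell_weights(grid, cell_a) - cell_weights(grid, cell_b)
  if (all(w == 0)) {
    # a cell contrasted with itself
    return(tibble::tibble(estimate = 0, se = 0, t = 0, df = Inf, p = 1))
  }
  ct <- suppressMessages(as.data.frame(
    emmeans::contrast(fit$emmeans, method = list(contrast = w))
  ))
  tibble::tibble(estimate = ct$estimate, se = ct$SE, t = ct$t.ratio,
                 df = ct$df, p = ct$p.value)
}

#' Spearman correlation between baseline power and behavior
#'
#' Rank correlation across subjects between a baseline band-power measure
#' (per-subject mean baseline-window band power, averaged across
#' hemispheres, per subregion) and a conflict-control measure (Simon effect
#' in RT or percent accuracy), with a two-sided p-value.
#'
#' @param baseline_power_by_subject,behavior_measure_by_subject Paired
#'   subject-level vectors, n >= 4.
#' @return One-row tibble: `rho`, `p`, `n`.
#' @export
baseline_behavior_correlation <- function(baseline_power_by_subject,
                                          behavior_measure_by_subject) {
  x <- baseline_power_by_subject
  y <- behavior_measure_by_subject
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) {
    stn_error("Spearman correlation needs at least 4 complete subject pairs.",
              "stnlfp_config_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stn_error("cannot rank-correlate a constant vector.",
              "stnlfp_degenerate_error")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p = unname(ct$p.value),
                 n = length(x))
}
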