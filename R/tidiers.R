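#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted band-power mixed model
#'
#' @param x An `stn_lfp_fit` from [fit_mixed()].
#' @param effects `"fixed"` for the Satterthwaite F table of the fixed
#'   terms, `"cells"` for the estimated marginal means of the 8 design
#'   cells (log scale), `"ran_pars"` for the random-effect SDs.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy stn_lfp_fit
#' @export
tidy.stn_lfp_fit <- function(x, effects = c("fixed", "cells", "ran_pars"),
                             ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    an <- as.data.frame(x$anova)
    tibble::tibble(
      term = rownames(an), statistic = an[["F value"]],
      df_num = an$NumDF, df_den = an$DenDF, p.value = an[["Pr(>F)"]]
    )
  } else if (effects == "cells") {
    emm <- as.data.frame(x$emmeans)
    tibble::tibble(
      subregion = as.character(emm$subregion),
      correspondence = as.character(emm$correspondence),
      hemisphere_rel = as.character(emm$hemisphere_rel),
      estimate = emm$emmean, std.error = emm$SE, df = emm$df
    )
  } else {
    vc <- as.data.frame(lme4::VarCorr(x$model))
    tibble::tibble(group = vc$grp, term = dplyr::coalesce(vc$var1, "sd"),
                   estimate = vc$sdcor)
  }
}

#' One-row fit summary of a band-power mixed model
#'
#' @param x An `stn_lfp_fit`.
#' @param ... Unused.
#' @return A tibble with the random-structure ladder step actually fit, the
#'   residual SD, REML criterion, log-likelihood and observation count.
#' @method glance stn_lfp_fit
#' @export
glance.stn_lfp_fit <- function(x, ...) {
  tibble::tibble(
    ladder_step = x$ladder_step,
    sigma = stats::sigma(x$model),
    REMLcrit = lme4::REMLcrit(x$model),
    logLik = as.numeric(stats::logLik(x$model)),
    nobs = stats::nobs(x$model),
    n_subjects = nlevels(droplevels(x$data$subject_id))
  )
}
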