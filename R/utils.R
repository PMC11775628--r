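#' @noRd
stn_error <- function(msg, class) {
  rlang::abort(msg, class = c(class, "stnlfp_error"))
}

#' Validate a categorical label against its allowed values
#' @noRd
check_label <- function(x, allowed, what) {
  if (length(x) != 1L || is.na(x) || !x %in% allowed) {
    stn_error(
      sprintf(
        "`%s` must be one of %s, got %s.",
        what, paste0("'", allowed, "'", collapse = ", "),
        if (length(x) == 1L) paste0("'", x, "'") else sprintf("length-%d input", length(x))
      ),
      "stnlfp_label_error"
    )
  }
  x
}

#' Vectorised label check (used by table validators)
#' @noRd
check_labels <- function(x, allowed, what) {
  bad <- !x %in% allowed
  if (any(bad)) {
    stn_error(
      sprintf("column `%s` contains invalid labels: %s",
              what, paste(unique(x[bad]), collapse = ", ")),
      "stnlfp_label_error"
    )
  }
  x
}

#' Check that a scalar is a positive finite number
#' @noRd
check_positive <- function(x, what, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stn_error(sprintf("`%s` must be a %s finite number.", what,
                      if (strict) "positive" else "non-negative"),
              "stnlfp_config_error")
  }
  x
}

SIDES <- c("left", "right")
SUBREGIONS <- c("dorsal", "ventral")
CORRESPONDENCE <- c("Cs", "NC")
HEMI_REL <- c("ipsilateral", "contralateral")
ACCURACY_LEVELS <- c("correct", "error", "omission", "too_early")

#' Draw a derived RNG sub-seed (kept below 2^31)
#' @noRd
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 10007L * as.integer(offset)) %% 2147483629L
}
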