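#' Draw ex-Gaussian reaction times (ms)
#' @noRd
rexgauss <- function(n, mu, sigma, tau) {
  rnorm(n, mu, sigma) + rexp(n, rate = 1 / tau)
}

#' Simulate Simon-task behavior for one subject
#'
#' Generates the per-trial event stream of the intraoperative Simon task for
#' one subject: `blocks_per_depth` blocks at each STN depth (dorsal first,
#' mirroring the surgical order), correspondence balanced to within one trial
#' per block, a variable 750--1250 ms intertrial interval, a 1000 ms response
#' deadline (omission beyond it), and ex-Gaussian reaction times with a mean
#' NC - Cs cost of `simon_rt_shift_ms`.
#'
#' Impulse-capture errors are implemented as a race: on NC trials an
#' automatic response toward the stimulus side, with its own (faster)
#' ex-Gaussian latency, wins when it beats the goal-directed response and
#' suppression fails (probability `p_impulse_error`). Captured trials are
#' fast errors, which produces the depressed fastest-bin accuracy on NC
#' trials that the conditional accuracy function must detect. A nonzero
#' `late_suppression` shrinks the RT cost on slow trials, producing a
#' negative-going final delta slope.
#'
#' Stimulus-onset times are seconds from the start of that depth's recording
#' (each depth has its own clock starting at 0).
#'
#' @param config An [sim_config()].
#' @param subject_id Subject identifier stored in the table.
#' @param p_impulse Subject-level impulse-capture probability; defaults to
#'   `config$p_impulse_error`.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A tibble with one row per trial: `subject_id`, `trial_id`,
#'   `block`, `depth`, `stim_onset_s`, `stim_side`, `correct_side`,
#'   `response_side`, `rt_ms`, `correspondence`, `accuracy`, `iti_prev_ms`.
#' @export
#' @examples
#' trials <- simulate_behavior(sim_config(trials_per_block = 16))
#' table(trials$correspondence, trials$accuracy)
simulate_behavior <- function(config, subject_id = "s01",
                              p_impulse = config$p_impulse_error,
                              seed = config$seed) {
  stopifnot(inherits(config, "stn_sim_config"))
  set.seed(seed)
  n <- config$trials_per_block
  blocks <- config$blocks_per_depth
  out <- vector("list", 2L * blocks)
  k <- 0L
  for (depth in SUBREGIONS) {
    t_cursor <- 3.0   # lead-in before the first trial of a depth, s
    for (b in seq_len(blocks)) {
      k <- k + 1L
      out[[k]] <- simulate_block(config, depth, b, n, p_impulse, t_cursor)
      t_cursor <- attr(out[[k]], "t_end") + 5.0   # between-block gap, s
      if (b == blocks) t_cursor <- 3.0            # next depth: new recording clock
    }
  }
  trials <- dplyr::bind_rows(out)
  attr(trials, "t_end") <- NULL
  trials$trial_id <- seq_len(nrow(trials))
  trials$subject_id <- as.character(subject_id)
  dplyr::relocate(trials, "subject_id", "trial_id")
}

#' @noRd
simulate_block <- function(config, depth, block, n, p_impulse, t_start) {
  n_half <- n %/% 2
  corr <- c(rep("Cs", n_half), rep("NC", n_half))
  if (n %% 2 == 1) corr <- c(corr, sample(CORRESPONDENCE, 1))
  corr <- sample(corr)
  stim_side <- sample(SIDES, n, replace = TRUE)
  correct_side <- ifelse(corr == "Cs", stim_side,
                         ifelse(stim_side == "left", "right", "left"))

  goal_rt <- rexgauss(n, config$rt_mu, config$rt_sigma, config$rt_tau)
  # selective late suppression: the NC cost shrinks on slow trials
  supp_w <- stats::plogis((goal_rt - (config$rt_mu + config$rt_tau + 50)) / 60)
  shift <- config$simon_rt_shift_ms * (1 - config$late_suppression * supp_w)
  goal_rt <- goal_rt + ifelse(corr == "NC", shift, 0)
  impulse_rt <- rexgauss(n, 300, 40, 60)

  anticipatory <- runif(n) < config$p_anticipatory
  too_early <- !anticipatory & runif(n) < config$p_anticipatory
  captured <- corr == "NC" & impulse_rt < goal_rt & impulse_rt <= 1000 &
    runif(n) < p_impulse & !anticipatory & !too_early
  lapse <- runif(n) < config$p_lapse

  rt <- goal_rt
  response <- correct_side
  accuracy <- rep("correct", n)

  rt[captured] <- impulse_rt[captured]
  response[captured] <- stim_side[captured]   # NC: stimulus side is the wrong side
  accuracy[captured] <- "error"

  plain <- !captured & !anticipatory & !too_early
  omitted <- plain & goal_rt > 1000
  accuracy[omitted] <- "omission"
  rt[omitted] <- NA_real_
  response[omitted] <- NA_character_

  lapsed <- plain & !omitted & lapse
  response[lapsed] <- ifelse(correct_side[lapsed] == "left", "right", "left")
  accuracy[lapsed] <- "error"

  rt[anticipatory] <- runif(sum(anticipatory), 50, 149)
  guess <- sample(SIDES, sum(anticipatory), replace = TRUE)
  response[anticipatory] <- guess
  accuracy[anticipatory] <- ifelse(guess == correct_side[anticipatory],
                                   "correct", "error")

  rt[too_early] <- NA_real_
  response[too_early] <- NA_character_
  accuracy[too_early] <- "too_early"

  iti <- runif(n, 750, 1250)
  elapsed <- ifelse(is.na(rt), 1000, rt)   # screen clears at response or deadline
  stim_onset <- t_start + cumsum(iti / 1000 + elapsed / 1000) - elapsed / 1000
  tbl <- tibble::tibble(
    trial_id = seq_len(n), block = block, depth = depth,
    stim_onset_s = stim_onset, stim_side = stim_side,
    correct_side = correct_side, response_side = response,
    rt_ms = rt, correspondence = corr, accuracy = accuracy,
    iti_prev_ms = iti
  )
  attr(tbl, "t_end") <- stim_onset[n] + elapsed[n] / 1000
  tbl
}
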