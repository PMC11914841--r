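#' Synthetic learner profile
#'
#' A learner agent whose probability of hitting a target is logistic in
#' the gap between its current skill and the scalar difficulty index, and
#' whose skill grows exponentially toward an asymptote with practice:
#' `skill(b) = asymptote - (asymptote - baseline) * (1 - learning_rate)^b`
#' after `b` blocks.
#'
#' @param baseline_skill Skill before any practice, on the
#'   [total_difficulty()] index scale.
#' @param asymptote_skill Skill approached with unlimited practice;
#'   must be at least `baseline_skill`.
#' @param learning_rate Per-block fraction of the remaining skill gap
#'   closed, in `[0, 1]`.
#' @param slope Logistic scale (index units per logit) of the success
#'   probability; larger = noisier mapping from skill gap to success.
#' @param fp_propensity Non-negative propensity to strike distractors.
#' @param periphery_penalty Non-negative logit penalty applied to targets
#'   spawned in the periphery of the working area.
#' @return An object of class `learner_profile`.
#' @export
learner_profile <- function(baseline_skill = 5, asymptote_skill = 16,
                            learning_rate = 0.05, slope = 2,
                            fp_propensity = 1, periphery_penalty = 0.5) {
  stopifnot(asymptote_skill >= baseline_skill,
            learning_rate >= 0, learning_rate <= 1,
            slope > 0, fp_propensity >= 0, periphery_penalty >= 0)
  structure(list(baseline_skill = baseline_skill,
                 asymptote_skill = asymptote_skill,
                 learning_rate = learning_rate,
                 slope = slope,
                 fp_propensity = fp_propensity,
                 periphery_penalty = periphery_penalty),
            class = "learner_profile")
}

#' @export
print.learner_profile <- function(x, ...) {
  cat(sprintf(
    "<learner_profile> skill %.1f -> %.1f, rate %.3f/block, slope %.2f\n",
    x$baseline_skill, x$asymptote_skill, x$learning_rate, x$slope))
  invisible(x)
}

learner_skill <- function(learner, block_index) {
  learner$asymptote_skill -
    (learner$asymptote_skill - learner$baseline_skill) *
    (1 - learner$learning_rate)^block_index
}

#' Success probability of a learner against a difficulty state
#'
#' `plogis((skill(block_index) - total_difficulty(state)) / slope)`:
#' strictly decreasing in the difficulty index, non-decreasing in
#' practice, always in (0, 1).
#'
#' @param learner A [learner_profile].
#' @param state A [difficulty_state].
#' @param block_index Number of blocks already played (0 = naive).
#' @return Probability in (0, 1).
#' @export
success_probability <- function(learner, state, block_index = 0) {
  skill <- learner_skill(learner, block_index)
  stats::plogis((skill - total_difficulty(state)) / learner$slope)
}

# draw spawn locations: uniform over the working square, with 30% of
# spawns pulled toward the regulator's bias region when one is set
draw_spawns <- function(n, state) {
  e <- working_extent(state)
  az <- stats::runif(n, -e, e)
  el <- stats::runif(n, -e, e)
  b <- state$spawn_bias
  if (!is.null(b) && n > 0) {
    biased <- stats::runif(n) < 0.3
    k <- sum(biased)
    if (k) {
      az[biased] <- pmin(e, pmax(-e, stats::rnorm(k, b[1L], 0.15 * e)))
      el[biased] <- pmin(e, pmax(-e, stats::rnorm(k, b[2L], 0.15 * e)))
    }
  }
  data.frame(az = az, el = el)
}

#' Simulate one block of play
#'
#' Draws [trials_for_block()] target trials. Each target spawns uniformly
#' in the working area (biased toward the regulator's focus region when
#' set) and is hit with the learner's [success_probability()], reduced by
#' `periphery_penalty` logits for peripheral spawns. Hit latencies are
#' uniform within the state's exposure window; latencies cannot exceed
#' the window, so slow responses are omissions by construction. False
#' positives are Poisson with rate `fp_propensity * (n_distractors / 23)
#' * (0.25 + 0.75 * salience_mix)`; each is low-salience with probability
#' `1.5 m / (1.5 m + (1 - m))` for mix `m` (target-like distractors are
#' disproportionately struck).
#'
#' @param learner A [learner_profile].
#' @param state A [difficulty_state].
#' @param block_index Block number (1-based).
#' @return A [block_log]. Uses the current RNG stream; seed it (or run
#'   inside [run_regulated_session()]) for reproducibility.
#' @export
simulate_block <- function(learner, state, block_index) {
  n <- trials_for_block(state)
  sp <- draw_spawns(n, state)
  edge <- 0.6 * working_extent(state)
  periph <- pmax(abs(sp$az), abs(sp$el)) > edge
  skill <- learner_skill(learner, block_index)
  logit <- (skill - total_difficulty(state)) / learner$slope -
    learner$periphery_penalty * periph
  hit <- stats::runif(n) < stats::plogis(logit)
  win <- exposure_window(state)
  trials <- data.frame(
    kind = ifelse(hit, "hit", "omission"),
    az = sp$az, el = sp$el,
    latency = ifelse(hit, stats::runif(n, 0.15 * win, win), NA_real_),
    salience = "none", stringsAsFactors = FALSE)
  lam <- learner$fp_propensity * (state$n_distractors / 23) *
    (0.25 + 0.75 * state$salience_mix)
  n_fp <- stats::rpois(1L, lam)
  if (n_fp > 0) {
    spf <- draw_spawns(n_fp, state)
    m <- state$salience_mix
    p_low <- if (m > 0) 1.5 * m / (1.5 * m + (1 - m)) else 0
    fp <- data.frame(
      kind = "false_positive", az = spf$az, el = spf$el,
      latency = NA_real_,
      salience = ifelse(stats::runif(n_fp) < p_low, "low", "high"),
      stringsAsFactors = FALSE)
    trials <- rbind(trials, fp)
  }
  block_log(block_index, trials, state)
}

#' Run a closed-loop regulated session
#'
#' The regulator's main loop: simulate a block under the current state,
#' diagnose it, classify its success rate into the too-easy / difficult /
#' too-difficult bands, and [adjust()] the state for the next block.
#'
#' @param learner A [learner_profile].
#' @param n_blocks Number of blocks to play (>= 1).
#' @param seed Integer seed; the whole session is reproducible from it.
#' @param state0 Starting [difficulty_state]; default [easiest_state()].
#' @return An object of class `session_log`: list with `blocks` (list of
#'   [block_log]) and `summary`, a data frame with one row per block
#'   (`block`, `n_targets`, `hits`, `false_positives`, `success_rate`,
#'   `verdict`, `difficulty`).
#' @export
run_regulated_session <- function(learner, n_blocks, seed,
                                  state0 = easiest_state()) {
  stopifnot(n_blocks >= 1)
  set.seed(as.integer(seed))
  state <- state0
  blocks <- vector("list", n_blocks)
  rows <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    log <- simulate_block(learner, state, b)
    d <- diagnose(log)
    verdict <- classify_block(d$success_rate)
    k <- log$trials$kind
    rows[[b]] <- data.frame(
      block = b,
      n_targets = sum(k %in% c("hit", "omission")),
      hits = sum(k == "hit"),
      false_positives = sum(k == "false_positive"),
      success_rate = d$success_rate,
      verdict = verdict,
      difficulty = total_difficulty(state),
      stringsAsFactors = FALSE)
    blocks[[b]] <- log
    state <- adjust(state, verdict, d)
  }
  structure(list(blocks = blocks,
                 summary = do.call(rbind, rows),
                 learner = learner, seed = as.integer(seed)),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<session_log> %d blocks, mean success %.1f%%, final difficulty %.2f\n",
    nrow(s), 100 * mean(s$success_rate), s$difficulty[nrow(s)]))
  invisible(x)
}

#' Default synthetic learner population
#'
#' Draws a heterogeneous cohort of [learner_profile]s. The default
#' constants were calibrated by simulation so that a cohort of 20
#' regulated learners starting from the easiest state reproduces the
#' intended session course: an early too-easy ramp, cohort-median success
#' entering the 60-80% band within roughly a dozen blocks, sustained band
#' occupancy thereafter, and a long-run mean success rate near the
#' regulator's 75% goal.
#'
#' @param n Number of learners.
#' @param seed Integer seed for the population draw.
#' @return List of `n` [learner_profile] objects.
#' @export
default_learner_population <- function(n = 20, seed = 1) {
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    base <- stats::rnorm(1, 6, 1.5)
    gain <- max(2, stats::rnorm(1, 20, 2.5))
    learner_profile(
      baseline_skill = base,
      asymptote_skill = base + gain,
      learning_rate = min(0.3, max(0.005, stats::rnorm(1, 0.025, 0.008))),
      slope = max(0.8, stats::rnorm(1, 2, 0.4)),
      fp_propensity = max(0, stats::rnorm(1, 1, 0.4)),
      periphery_penalty = max(0, stats::rnorm(1, 0.5, 0.2)))
  })
}

#' Cohort success-rate matrix
#'
#' @param sessions List of `session_log`s of equal length.
#' @return Matrix blocks x learners of per-block success rates.
#' @export
cohort_success_matrix <- function(sessions) {
  sapply(sessions, function(s) s$summary$success_rate)
}

#' Per-block cohort success summary
#'
#' Median and quartiles of the success rate across learners at each
#' block, the shape of the study's feasibility figure.
#'
#' @param sessions List of `session_log`s.
#' @return Data frame with `block`, `q1`, `median`, `q3`.
#' @export
block_success_table <- function(sessions) {
  m <- cohort_success_matrix(sessions)
  qs <- t(apply(m, 1L, stats::quantile, probs = c(0.25, 0.5, 0.75)))
  data.frame(block = seq_len(nrow(m)),
             q1 = qs[, 1L], median = qs[, 2L], q3 = qs[, 3L])
}

#' First block whose cohort-median success rate enters a band
#'
#' @param sessions List of `session_log`s.
#' @param band Length-2 numeric band, default `c(0.6, 0.8)`.
#' @return Integer block index, or `NA` if the median never enters.
#' @export
time_to_band <- function(sessions, band = c(0.6, 0.8)) {
  med <- block_success_table(sessions)$median
  idx <- which(med >= band[1L] & med <= band[2L])
  if (length(idx)) idx[1L] else NA_integer_
}

#' Share of blocks whose cohort-median success rate lies in a band
#'
#' @param sessions List of `session_log`s.
#' @param blocks Block indices to assess, default `12:55`.
#' @param band Length-2 numeric band, default `c(0.6, 0.8)`.
#' @return Fraction in `[0, 1]`.
#' @export
band_occupancy <- function(sessions, blocks = 12:55, band = c(0.6, 0.8)) {
  med <- block_success_table(sessions)$median
  blocks <- blocks[blocks <= length(med)]
  mean(med[blocks] >= band[1L] & med[blocks] <= band[2L])
}
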