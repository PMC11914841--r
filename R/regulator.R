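#' Adjustable game difficulty state
#'
#' The regulator manipulates five parameter groups of the whack-a-mole
#' task: target exposure time (shorter = harder), working-area extent
#' (wider = harder), number of distractor moles, the fraction of
#' low-salience-contrast (target-like) distractors, and the cue mode
#' (combined visual + auditory help, spatial auditory only, or none).
#'
#' @param exposure_level Integer 0..6; higher means a shorter on-screen
#'   exposure window for the target.
#' @param area_level Integer 0..6; higher means a wider working area.
#' @param n_distractors Integer 0..23 distractor moles per trial.
#' @param salience_mix Fraction in `[0, 1]` of distractors with low
#'   salience contrast (visually close to the target).
#' @param cue_mode One of `"visual_and_auditory"` (easiest),
#'   `"auditory_spatial"`, `"none"` (hardest).
#' @param spawn_bias Optional length-2 numeric (azimuth, elevation) in the
#'   normalized working square toward which target spawns are biased, used
#'   by the regulator to train a failing region; `NULL` for uniform spawns.
#'
#' @return An object of class `difficulty_state` (a list).
#' @seealso [total_difficulty()], [adjust()], [trials_for_block()]
#' @export
difficulty_state <- function(exposure_level = 0L, area_level = 0L,
                             n_distractors = 0L, salience_mix = 0,
                             cue_mode = c("visual_and_auditory",
                                          "auditory_spatial", "none"),
                             spawn_bias = NULL) {
  cue_mode <- match.arg(cue_mode)
  stopifnot(exposure_level >= 0, exposure_level <= 6,
            area_level >= 0, area_level <= 6,
            n_distractors >= 0, n_distractors <= 23,
            salience_mix >= 0, salience_mix <= 1)
  if (!is.null(spawn_bias)) {
    stopifnot(length(spawn_bias) == 2, all(abs(spawn_bias) <= 1))
    spawn_bias <- as.numeric(spawn_bias)
  }
  structure(list(exposure_level = as.integer(exposure_level),
                 area_level = as.integer(area_level),
                 n_distractors = as.integer(n_distractors),
                 salience_mix = as.numeric(salience_mix),
                 cue_mode = cue_mode,
                 spawn_bias = spawn_bias),
            class = "difficulty_state")
}

#' @export
print.difficulty_state <- function(x, ...) {
  cat(sprintf(
    "<difficulty_state> exposure=%d area=%d distractors=%d salience=%.2f cue=%s (index %.2f)\n",
    x$exposure_level, x$area_level, x$n_distractors, x$salience_mix,
    x$cue_mode, total_difficulty(x)))
  invisible(x)
}

#' Easiest difficulty state
#' @return A [difficulty_state] with every dimension at its easiest level.
#' @export
easiest_state <- function() difficulty_state()

#' Hardest difficulty state
#' @return A [difficulty_state] with every dimension at its hardest level.
#' @export
hardest_state <- function() {
  difficulty_state(exposure_level = 6L, area_level = 6L, n_distractors = 23L,
                   salience_mix = 1, cue_mode = "none")
}

cue_level <- function(state) {
  match(state$cue_mode,
        c("visual_and_auditory", "auditory_spatial", "none")) - 1L
}

#' Scalar total difficulty index
#'
#' Sum of the per-dimension difficulty levels, on a common scale where one
#' regulator step on any dimension moves the index by one unit: exposure
#' and area levels count directly, distractors count 1 per 4 moles,
#' salience mix counts 2 at full mix (one step = 0.25 mix = 0.5 units),
#' and cue withdrawal counts 1 per stage. Range 0 to 21.75.
#'
#' @param state A [difficulty_state].
#' @return Non-negative scalar.
#' @export
total_difficulty <- function(state) {
  state$exposure_level + state$area_level + state$n_distractors / 4 +
    2 * state$salience_mix + cue_level(state)
}

#' Working-area half-extent of a difficulty state
#'
#' The working area is a square `[-e, e]^2` in normalized azimuth /
#' elevation coordinates; `e` grows linearly with `area_level` from 0.4
#' (easiest) to 1 (hardest).
#'
#' @param state A [difficulty_state].
#' @return Half-extent `e` in `[0.4, 1]`.
#' @export
working_extent <- function(state) 0.4 + 0.1 * state$area_level

#' Target exposure window of a difficulty state
#'
#' Maps `exposure_level` monotonically down from 1.6 s (easiest) to 0.4 s
#' (hardest); the upper bound on hit latency before a target counts as an
#' omission.
#'
#' @param state A [difficulty_state].
#' @return Exposure window in seconds.
#' @export
exposure_window <- function(state) 1.6 - 0.2 * state$exposure_level

#' Number of target trials for the next block
#'
#' Blocks contain 1 to 24 target moles depending on the level of
#' difficulty: `4 + 2 * total_difficulty`, rounded and clamped to
#' `[1, 24]`, so harder states give more practice trials per block.
#'
#' @param state A [difficulty_state].
#' @return Integer in `[1, 24]`.
#' @export
trials_for_block <- function(state) {
  as.integer(min(24, max(1, round(4 + 2 * total_difficulty(state)))))
}

#' One block's trial events
#'
#' @param block_index Integer block number (1-based).
#' @param trials Data frame of trial events with columns `kind`
#'   (`"hit"`, `"omission"`, `"false_positive"`), `az`, `el` (spawn
#'   location in the normalized working square), `latency` (seconds,
#'   `NA` unless a hit) and `salience` (`"high"`/`"low"` for false
#'   positives, `"none"` otherwise).
#' @param state_used The [difficulty_state] the block was played under.
#' @return An object of class `block_log`.
#' @export
block_log <- function(block_index, trials, state_used) {
  stopifnot(is.data.frame(trials),
            all(c("kind", "az", "el", "latency", "salience") %in%
                  names(trials)))
  # canonical column set/typing so serialization round-trips exactly
  trials <- data.frame(kind = as.character(trials$kind),
                       az = as.numeric(trials$az),
                       el = as.numeric(trials$el),
                       latency = as.numeric(trials$latency),
                       salience = as.character(trials$salience),
                       stringsAsFactors = FALSE)
  n_targets <- sum(trials$kind %in% c("hit", "omission"))
  if (n_targets < 1 || n_targets > 24)
    stop("block_log integrity error: target trials must number 1 to 24",
         call. = FALSE)
  bad_lat <- xor(trials$kind == "hit", !is.na(trials$latency))
  if (any(bad_lat))
    stop("block_log integrity error: latency present iff kind is hit",
         call. = FALSE)
  bad_sal <- xor(trials$kind == "false_positive", trials$salience != "none")
  if (any(bad_sal))
    stop("block_log integrity error: salience set iff kind is false_positive",
         call. = FALSE)
  structure(list(block_index = as.integer(block_index),
                 trials = trials, state_used = state_used),
            class = "block_log")
}

#' Block success rate
#'
#' The ratio between the number of target moles accurately hit and the
#' number of target trials in the block. False positives (hit distractors)
#' are separate events and enter neither numerator nor denominator.
#'
#' @param log A [block_log].
#' @return Fraction in `[0, 1]`.
#' @export
success_rate <- function(log) {
  k <- log$trials$kind
  n_targets <- sum(k %in% c("hit", "omission"))
  if (n_targets == 0) stop("success_rate: no target trials", call. = FALSE)
  sum(k == "hit") / n_targets
}

#' Classify a block by its success rate
#'
#' Band mapping used by the regulator: above 75% the game was too easy;
#' from 50% to 75% (both boundaries included) it was difficult, the
#' intended operating band; below 50% it was excessively difficult.
#'
#' @param rate Success rate in `[0, 1]`.
#' @return One of `"too_easy"`, `"difficult"`, `"too_difficult"`.
#' @export
classify_block <- function(rate) {
  if (!is.finite(rate) || rate < 0 || rate > 1)
    stop("classify_block: rate must lie in [0, 1]", call. = FALSE)
  if (rate > 0.75) "too_easy"
  else if (rate >= 0.50) "difficult"
  else "too_difficult"
}

#' Diagnose a block's error structure
#'
#' Computes the indicators the regulator uses to decide which difficulty
#' dimension is responsible for the observed success rate: the omission
#' fraction, where omissions occurred (periphery = spawn location beyond
#' 60% of the current working extent on either axis), the false-positive
#' count, and how many false positives were low-salience (target-like)
#' distractors.
#'
#' @param log A [block_log].
#' @return A list of class `block_diagnostics` with fields
#'   `success_rate`, `omission_fraction`, `false_positive_count`,
#'   `omission_periphery_share`, `fp_low_salience_share`, and
#'   `omission_centroid` (mean omission spawn location, `NULL` if none).
#' @export
diagnose <- function(log) {
  tr <- log$trials
  k <- tr$kind
  n_targets <- sum(k %in% c("hit", "omission"))
  om <- tr[k == "omission", , drop = FALSE]
  fp <- tr[k == "false_positive", , drop = FALSE]
  edge <- 0.6 * working_extent(log$state_used)
  periph <- function(d) pmax(abs(d$az), abs(d$el)) > edge
  structure(list(
    success_rate = sum(k == "hit") / n_targets,
    omission_fraction = nrow(om) / n_targets,
    false_positive_count = nrow(fp),
    omission_periphery_share =
      if (nrow(om)) mean(periph(om)) else 0,
    fp_low_salience_share =
      if (nrow(fp)) mean(fp$salience == "low") else 0,
    omission_centroid =
      if (nrow(om)) c(mean(om$az), mean(om$el)) else NULL),
    class = "block_diagnostics")
}

# ordered list of "make harder" moves; cues are help, so help is
# withdrawn first, target-like distractors added last
harder_moves <- function(state) {
  list(
    cue = if (cue_level(state) < 2L) function(s) {
      s$cue_mode <- c("auditory_spatial", "none")[cue_level(s) + 1L]; s
    },
    exposure = if (state$exposure_level < 6L) function(s) {
      s$exposure_level <- s$exposure_level + 1L; s
    },
    area = if (state$area_level < 6L) function(s) {
      s$area_level <- s$area_level + 1L; s
    },
    distractors = if (state$n_distractors < 23L) function(s) {
      s$n_distractors <- min(23L, s$n_distractors + 4L); s
    },
    salience = if (state$salience_mix < 1) function(s) {
      s$salience_mix <- min(1, s$salience_mix + 0.25); s
    })
}

#' Adjust the difficulty state for the next block
#'
#' Deterministic decision table. On `too_easy` the first available
#' dimension in the priority order cue withdrawal, exposure shortening,
#' area widening, more distractors, more target-like distractors is
#' stepped one level harder (two dimensions when the block was perfect).
#' On `too_difficult` the dimension implicated by the diagnostics is
#' stepped easier: mostly-peripheral omissions shrink the area and
#' restore one cue stage; mostly low-salience false positives reduce the
#' salience mix (or the distractor count once the mix is zero); otherwise
#' the exposure window is lengthened, falling back through area,
#' distractors and cues. On `difficult` (the operating band) no level
#' changes; only the spawn bias is re-aimed at the centroid of the
#' block's omissions so the failing region gets practice. All fields are
#' clamped to their bounds; at a bound the move silently falls through to
#' the next dimension (or leaves the state unchanged).
#'
#' @param state Current [difficulty_state].
#' @param verdict A verdict from [classify_block()].
#' @param diagnostics A `block_diagnostics` from [diagnose()].
#' @return The next block's [difficulty_state].
#' @export
adjust <- function(state, verdict, diagnostics) {
  verdict <- match.arg(verdict, c("too_easy", "difficult", "too_difficult"))
  s <- state
  if (verdict == "too_easy") {
    n_steps <- if (diagnostics$success_rate >= 1) 2L else 1L
    for (i in seq_len(n_steps)) {
      mv <- Filter(Negate(is.null), harder_moves(s))
      if (!length(mv)) break
      s <- mv[[1L]](s)
    }
  } else if (verdict == "too_difficult") {
    if (diagnostics$omission_periphery_share >= 0.5 &&
        (s$area_level > 0L || cue_level(s) > 0L)) {
      if (s$area_level > 0L) s$area_level <- s$area_level - 1L
      if (cue_level(s) > 0L)
        s$cue_mode <- c("visual_and_auditory", "auditory_spatial")[cue_level(s)]
    } else if (diagnostics$fp_low_salience_share >= 0.5 &&
               diagnostics$false_positive_count > 0 &&
               (s$salience_mix > 0 || s$n_distractors > 0L)) {
      if (s$salience_mix > 0) s$salience_mix <- max(0, s$salience_mix - 0.25)
      else s$n_distractors <- max(0L, s$n_distractors - 4L)
    } else if (s$exposure_level > 0L) {
      s$exposure_level <- s$exposure_level - 1L
    } else if (s$area_level > 0L) {
      s$area_level <- s$area_level - 1L
    } else if (s$n_distractors > 0L) {
      s$n_distractors <- max(0L, s$n_distractors - 4L)
    } else if (cue_level(s) > 0L) {
      s$cue_mode <- c("visual_and_auditory", "auditory_spatial")[cue_level(s)]
    } else if (s$salience_mix > 0) {
      s$salience_mix <- max(0, s$salience_mix - 0.25)
    }
  } else { # difficult: stay, fine-tune spawn bias toward the failing region
    om <- state$spawn_bias
    s$spawn_bias <- om
    d <- diagnostics
    if (d$omission_fraction > 0 && !is.null(d$omission_centroid))
      s$spawn_bias <- d$omission_centroid
  }
  s
}
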