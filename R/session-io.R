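#' Write a session log as JSON lines
#'
#' Serializes a `session_log` as line-delimited JSON: one session header
#' record followed by one record per block (trial events in order plus
#' the difficulty state the block was played under). Numbers are written
#' at full precision so [read_session_log()] restores the session
#' exactly.
#'
#' @param session A `session_log` from [run_regulated_session()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(session, path) {
  if (!inherits(session, "session_log") || length(session$blocks) < 1)
    stop("write_session_log: need a session_log with at least one block",
         call. = FALSE)
  lines <- character(1L + length(session$blocks))
  lines[1L] <- jsonlite::toJSON(
    list(record = "session", seed = session$seed,
         learner = unclass(session$learner)),
    auto_unbox = TRUE, digits = I(17), null = "null")
  for (i in seq_along(session$blocks)) {
    b <- session$blocks[[i]]
    lines[i + 1L] <- jsonlite::toJSON(
      list(record = "block", block_index = b$block_index,
           state_used = unclass(b$state_used),
           trials = b$trials),
      auto_unbox = TRUE, digits = I(17), dataframe = "columns",
      null = "null")
  }
  writeLines(lines, path)
  invisible(path)
}

rebuild_state <- function(x) {
  difficulty_state(exposure_level = x$exposure_level,
                   area_level = x$area_level,
                   n_distractors = x$n_distractors,
                   salience_mix = x$salience_mix,
                   cue_mode = x$cue_mode,
                   spawn_bias = x$spawn_bias)
}

#' Read a session log written by [write_session_log()]
#'
#' @param path Path to a JSON-lines session log.
#' @return A `session_log`; the inverse of [write_session_log()].
#' @export
read_session_log <- function(path) {
  lines <- readLines(path)
  if (!length(lines))
    stop("read_session_log format error: empty file", call. = FALSE)
  recs <- lapply(lines, jsonlite::fromJSON)
  if (!identical(recs[[1L]]$record, "session"))
    stop("read_session_log format error: missing session header record",
         call. = FALSE)
  learner <- do.call(learner_profile, recs[[1L]]$learner)
  blocks <- lapply(recs[-1L], function(r) {
    if (!identical(r$record, "block"))
      stop(sprintf("read_session_log format error: unknown record type '%s'",
                   as.character(r$record)[1L]), call. = FALSE)
    tr <- as.data.frame(r$trials, stringsAsFactors = FALSE)
    bad <- setdiff(unique(tr$kind), c("hit", "omission", "false_positive"))
    if (length(bad))
      stop(sprintf("read_session_log format error: unknown event type '%s'",
                   bad[1L]), call. = FALSE)
    if (is.null(tr$latency)) tr$latency <- NA_real_
    tr$latency <- as.numeric(tr$latency)
    block_log(r$block_index, tr, rebuild_state(r$state_used))
  })
  rows <- lapply(blocks, function(b) {
    k <- b$trials$kind
    sr <- sum(k == "hit") / sum(k %in% c("hit", "omission"))
    data.frame(block = b$block_index,
               n_targets = sum(k %in% c("hit", "omission")),
               hits = sum(k == "hit"),
               false_positives = sum(k == "false_positive"),
               success_rate = sr,
               verdict = classify_block(sr),
               difficulty = total_difficulty(b$state_used),
               stringsAsFactors = FALSE)
  })
  structure(list(blocks = blocks, summary = do.call(rbind, rows),
                 learner = learner, seed = as.integer(recs[[1L]]$seed)),
            class = "session_log")
}

#' Read a long-format outcome table
#'
#' Expects comma-separated text with header
#' `participant_id,time_point,outcome_name,value`: one assessment record
#' per row, time points `T0`/`T1`/`T2`, missing values left empty (never
#' coded as zero).
#'
#' @param source Path to a CSV file, or a connection.
#' @return An `outcome_table` (long data frame).
#' @export
read_outcome_table <- function(source) {
  df <- utils::read.csv(source, header = TRUE, stringsAsFactors = FALSE)
  need <- c("participant_id", "time_point", "outcome_name", "value")
  if (!all(need %in% names(df))) {
    if (any(c("T0", "T1", "T2") %in% names(df)))
      stop(paste("outcome table format error: wide-format input;",
                 "provide long format participant_id,time_point,outcome_name,value"),
           call. = FALSE)
    stop(sprintf("outcome table format error: missing column(s) %s",
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  bad_tp <- setdiff(unique(df$time_point), c("T0", "T1", "T2"))
  if (length(bad_tp))
    stop(sprintf("outcome table integrity error: unknown time point '%s'",
                 bad_tp[1L]), call. = FALSE)
  key <- paste(df$participant_id, df$time_point, df$outcome_name)
  if (anyDuplicated(key))
    stop(sprintf(
      "outcome table integrity error: duplicate record for (%s)",
      key[duplicated(key)][1L]), call. = FALSE)
  df$value <- as.numeric(df$value)
  structure(df[, need], class = c("outcome_table", "data.frame"))
}

#' Write an outcome table as long-format CSV
#'
#' @param table An `outcome_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_outcome_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML key-value file; keys present override the package defaults from
#' [default_run_config()], unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A validated run configuration list (see
#'   [default_run_config()]).
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop(sprintf("run config format error: unknown key(s) %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  cfg[names(user)] <- user
  validate_run_config(cfg)
}
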