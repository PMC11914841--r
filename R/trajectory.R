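#' Construct a controller trajectory
#'
#' A trajectory is the time-stamped 3D position record of one hand-held VR
#' controller during a drawing task, nominally sampled at 60 Hz in the
#' headset world frame (metres, seconds).
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing,
#'   non-negative, finite.
#' @param x,y,z Numeric vectors of controller position in metres.
#' @param nominal_rate Nominal sampling rate in Hz. Default 60.
#' @param task Shape label of the drawing task, `"line"` or `"circle"`.
#' @param hand `"dominant"` or `"nondominant"`.
#'
#' @return An object of class `trajectory`: a data frame with columns
#'   `t`, `x`, `y`, `z` and attributes `nominal_rate`, `task`, `hand`.
#' @export
trajectory <- function(t, x, y, z, nominal_rate = 60,
                       task = c("line", "circle"),
                       hand = c("dominant", "nondominant")) {
  task <- match.arg(task)
  hand <- match.arg(hand)
  if (length(t) < 2L)
    stop("trajectory integrity error: fewer than 2 samples", call. = FALSE)
  n <- length(t)
  if (length(x) != n || length(y) != n || length(z) != n)
    stop("trajectory format error: t, x, y, z must have equal length",
         call. = FALSE)
  if (!all(is.finite(t)) || any(t < 0))
    stop("trajectory integrity error: timestamps must be finite and non-negative",
         call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    stop("trajectory integrity error: positions must be finite", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L] + 1L
    stop(sprintf(
      "trajectory integrity error: non-increasing timestamp at row %d", bad),
      call. = FALSE)
  }
  med <- stats::median(dt)
  if (abs(med - 1 / nominal_rate) > 0.2 / nominal_rate)
    stop(sprintf(paste0(
      "trajectory integrity error: median sampling interval %.4fs is not ",
      "within 20%% of 1/%g s"), med, nominal_rate), call. = FALSE)
  out <- data.frame(t = as.numeric(t), x = as.numeric(x),
                    y = as.numeric(y), z = as.numeric(z))
  structure(out,
            nominal_rate = nominal_rate, task = task, hand = hand,
            class = c("trajectory", "data.frame"))
}

#' @export
print.trajectory <- function(x, ...) {
  qr <- attr(x, "quality")
  cat(sprintf("<trajectory> %d samples, %.2f s, task=%s, hand=%s, %g Hz\n",
              nrow(x), x$t[nrow(x)] - x$t[1L], attr(x, "task"),
              attr(x, "hand"), attr(x, "nominal_rate")))
  if (!is.null(qr))
    cat(sprintf("  quality: %d samples, %.2f s, %d gap(s)\n",
                qr$n_samples, qr$duration, qr$n_gaps))
  invisible(x)
}

#' Duration of a trajectory in seconds
#' @param traj A `trajectory`.
#' @return Duration in seconds.
#' @export
trajectory_duration <- function(traj) {
  traj$t[nrow(traj)] - traj$t[1L]
}

#' Read a trajectory from a CSV export file
#'
#' Reads the comma-separated controller export produced by the headset:
#' a header row and columns `t,x,y,z` (seconds and metres). Millisecond
#' timestamps are auto-detected (median step above 1) and converted to
#' seconds, so reading is idempotent with respect to units. A preliminary
#' quality report (sample count, duration, number of sampling gaps larger
#' than twice the nominal interval) is attached as attribute `"quality"`,
#' standing in for the visual pre-screen an assessor would perform.
#'
#' @param source Path to a CSV file, or a connection.
#' @param nominal_rate Nominal sampling rate in Hz (default 60).
#' @param task,hand Passed to [trajectory()].
#' @return A [trajectory] with a `"quality"` attribute (list with
#'   `n_samples`, `duration`, `n_gaps`).
#' @export
read_trajectory <- function(source, nominal_rate = 60, task = "line",
                            hand = "dominant") {
  df <- utils::read.csv(source, header = TRUE)
  need <- c("t", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("trajectory format error: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  tt <- as.numeric(df$t)
  if (length(tt) >= 2 && stats::median(diff(tt)) > 1)
    tt <- tt / 1000  # millisecond export
  traj <- trajectory(tt, df$x, df$y, df$z, nominal_rate = nominal_rate,
                     task = task, hand = hand)
  dt <- diff(traj$t)
  attr(traj, "quality") <- list(
    n_samples = nrow(traj),
    duration = trajectory_duration(traj),
    n_gaps = sum(dt > 2 / nominal_rate))
  traj
}

#' Write a trajectory to a CSV export file
#'
#' @param traj A [trajectory].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("t", "x", "y", "z")], path,
                   row.names = FALSE)
  invisible(path)
}
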