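#' Ideal line shape
#'
#' @param p0,p1 Length-3 numeric endpoints in metres; must differ.
#' @return An object of class `ideal_shape`, kind `"line"`.
#' @export
ideal_line <- function(p0 = c(0, 0, 0), p1 = c(0.3, 0, 0)) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  stopifnot(length(p0) == 3, length(p1) == 3)
  if (sqrt(sum((p1 - p0)^2)) == 0)
    stop("ideal_line: endpoints must differ", call. = FALSE)
  structure(list(kind = "line", p0 = p0, p1 = p1), class = "ideal_shape")
}

#' Ideal circle shape
#'
#' @param center Length-3 numeric centre in metres.
#' @param radius Radius in metres, > 0.
#' @param normal Length-3 plane normal; normalized internally.
#' @return An object of class `ideal_shape`, kind `"circle"`.
#' @export
ideal_circle <- function(center = c(0, 0, 0), radius = 0.15,
                         normal = c(0, 0, 1)) {
  stopifnot(radius > 0, length(center) == 3, length(normal) == 3)
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop("ideal_circle: zero normal", call. = FALSE)
  structure(list(kind = "circle", center = as.numeric(center),
                 radius = radius, normal = as.numeric(normal) / nn),
            class = "ideal_shape")
}

# zero-phase pass with mean-centering and odd-reflection padding to kill
# the zero-initial-state startup transient of a causal IIR run
zero_phase <- function(x, bf, n_pad) {
  mu <- x[1L]
  xc <- x - mu
  n <- length(xc)
  n_pad <- min(n - 1L, n_pad)
  head_pad <- 2 * xc[1L] - xc[(n_pad + 1L):2L]
  tail_pad <- 2 * xc[n] - xc[(n - 1L):(n - n_pad)]
  y <- signal::filtfilt(bf, c(head_pad, xc, tail_pad))
  y[(n_pad + 1L):(n_pad + n)] + mu
}

#' Zero-phase Butterworth low-pass filter of a trajectory
#'
#' Each coordinate is filtered forward and backward with a Butterworth
#' low-pass (default 10 Hz cutoff, 4th order, at the 60 Hz nominal rate),
#' the standard smoothing step for movement kinematics; the zero-phase
#' double pass squares the magnitude response and leaves timestamps
#' untouched.
#'
#' @param traj A [trajectory].
#' @param cutoff_hz Cutoff frequency in Hz, must be below Nyquist.
#' @param order Filter order of the single pass (default 4).
#' @return The filtered [trajectory].
#' @export
lowpass_filter <- function(traj, cutoff_hz = 10, order = 4) {
  fs <- attr(traj, "nominal_rate")
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop("lowpass_filter parameter error: cutoff must lie in (0, Nyquist)",
         call. = FALSE)
  if (nrow(traj) < 3 * (order + 1))
    stop("lowpass_filter: trajectory shorter than filter warm-up",
         call. = FALSE)
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  n_pad <- max(3L * (order + 1L), as.integer(fs))
  for (col in c("x", "y", "z"))
    traj[[col]] <- zero_phase(traj[[col]], bf, n_pad)
  traj
}

#' Analytic magnitude response of the zero-phase Butterworth pass
#'
#' Closed-form gain of the digital (bilinear-transform, prewarped)
#' Butterworth low-pass applied forward and backward, for checking the
#' filter implementation against theory.
#'
#' @param f Frequency in Hz at which to evaluate.
#' @param fs Sampling rate in Hz.
#' @param cutoff_hz Cutoff in Hz.
#' @param order Single-pass order.
#' @return Gain of the double pass (single-pass magnitude squared).
#' @export
butter_gain <- function(f, fs, cutoff_hz, order = 4) {
  w <- tan(pi * f / fs) / tan(pi * cutoff_hz / fs)
  (1 / (1 + w^(2 * order)))  # |H|^2
}

#' Speed profile of a trajectory
#'
#' Speed is the Euclidean norm of the first derivative of controller
#' position, computed by central finite differences on the sample grid
#' (one-sided at the ends).
#'
#' @param traj A [trajectory] (normally already low-pass filtered).
#' @param gap_tol Relative tolerance on sampling gaps: any interval more
#'   than `gap_tol` times the nominal interval is an error.
#' @return A data frame of class `speed_series` with columns `t`, `v`.
#' @export
speed_profile <- function(traj, gap_tol = 3) {
  if (nrow(traj) < 3)
    stop("speed_profile: need at least 3 samples", call. = FALSE)
  fs <- attr(traj, "nominal_rate")
  dt <- diff(traj$t)
  if (any(dt > gap_tol / fs))
    stop("speed_profile: sampling gap beyond tolerance; resample first",
         call. = FALSE)
  p <- as.matrix(traj[, c("x", "y", "z")])
  n <- nrow(p)
  d <- matrix(0, n, 3L)
  d[1L, ] <- (p[2L, ] - p[1L, ]) / (traj$t[2L] - traj$t[1L])
  d[n, ] <- (p[n, ] - p[n - 1L, ]) / (traj$t[n] - traj$t[n - 1L])
  i <- 2L:(n - 1L)
  d[i, ] <- (p[i + 1L, ] - p[i - 1L, ]) / (traj$t[i + 1L] - traj$t[i - 1L])
  structure(data.frame(t = traj$t, v = sqrt(rowSums(d^2))),
            nominal_rate = fs,
            class = c("speed_series", "data.frame"))
}

# principal direction of the orthogonal residuals (uncentered), i.e. the
# in-plane normal of the 2D assessment plane for the line task
line_residuals_2d <- function(p, p0, u) {
  q <- sweep(p, 2L, p0)
  r <- q - outer(as.vector(q %*% u), u)        # component orthogonal to line
  m <- crossprod(r) / nrow(r)
  if (max(abs(m)) < 1e-18) return(rep(0, nrow(r)))
  w <- eigen(m, symmetric = TRUE)$vectors[, 1L]
  as.vector(r %*% w)
}

#' Deviation of a trajectory from its ideal shape
#'
#' Root-mean-square orthogonal deviation of the samples from the ideal
#' path, in centimetres. For the line task the deviation is assessed in
#' 2D: samples are projected onto the plane spanned by the line direction
#' and the dominant orthogonal variance direction, and the in-plane
#' distance from the line is used. For the circle task the full 3D
#' distance to the ideal circle (in-plane radial error and out-of-plane
#' offset combined) is used.
#'
#' @param traj A [trajectory].
#' @param ideal An [ideal_shape] matching the trajectory's task.
#' @return RMS deviation in cm.
#' @export
path_error <- function(traj, ideal) {
  if (!inherits(ideal, "ideal_shape"))
    stop("path_error: ideal must be an ideal_shape", call. = FALSE)
  if (attr(traj, "task") != ideal$kind)
    stop(sprintf("path_error: trajectory task '%s' does not match shape '%s'",
                 attr(traj, "task"), ideal$kind), call. = FALSE)
  p <- as.matrix(traj[, c("x", "y", "z")])
  if (ideal$kind == "line") {
    u <- ideal$p1 - ideal$p0
    u <- u / sqrt(sum(u^2))
    dev_m <- line_residuals_2d(p, ideal$p0, u)
  } else {
    q <- sweep(p, 2L, ideal$center)
    off <- as.vector(q %*% ideal$normal)
    q_in <- q - outer(off, ideal$normal)
    dev_m <- sqrt((sqrt(rowSums(q_in^2)) - ideal$radius)^2 + off^2)
  }
  100 * sqrt(mean(dev_m^2))
}

#' Speed-accuracy trade-off (SAT)
#'
#' The ratio between speed and error: mean speed over the task (path
#' length divided by duration, in cm/s) divided by the RMS deviation from
#' the ideal path (cm), floored at `error_floor_cm` to guard perfect
#' traces. Higher SAT reflects a more efficient balance of speed and
#' accuracy. The absolute scale is arbitrary units.
#'
#' @param traj A filtered [trajectory].
#' @param ideal An [ideal_shape].
#' @param error_floor_cm Lower bound on the error term in cm (default 0.1).
#' @return SAT in arbitrary units (> 0).
#' @export
compute_sat <- function(traj, ideal, error_floor_cm = 0.1) {
  stopifnot(error_floor_cm > 0)
  dur <- trajectory_duration(traj)
  if (dur <= 0) stop("compute_sat: zero-duration trajectory", call. = FALSE)
  p <- as.matrix(traj[, c("x", "y", "z")])
  path_cm <- 100 * sum(sqrt(rowSums(diff(p)^2)))
  mean_speed_cms <- path_cm / dur
  err <- max(path_error(traj, ideal), error_floor_cm)
  mean_speed_cms / err
}

#' Normalized magnitude spectrum of a speed signal
#'
#' Zero-padded FFT magnitude of the speed series, normalized by its value
#' at zero frequency so the spectrum starts at 1.
#'
#' @param ss A `speed_series` from [speed_profile()].
#' @param pad_factor Zero-padding factor applied to the next power of two
#'   (default 4).
#' @return List of class `speed_spectrum` with `omega` (Hz, from 0 to
#'   Nyquist) and `V` (normalized magnitude, `V[1] == 1`).
#' @export
speed_spectrum <- function(ss, pad_factor = 4) {
  v <- ss$v
  if (length(v) < 8)
    stop("speed_spectrum: need at least 8 samples", call. = FALSE)
  fs <- attr(ss, "nominal_rate")
  if (is.null(fs)) fs <- 1 / stats::median(diff(ss$t))
  nfft <- pad_factor * 2^ceiling(log2(length(v)))
  V <- abs(stats::fft(c(v, rep(0, nfft - length(v)))))
  if (V[1L] == 0)
    stop("speed_spectrum: all-zero speed signal, normalization undefined",
         call. = FALSE)
  keep <- seq_len(nfft %/% 2 + 1L)
  structure(list(omega = (keep - 1L) * fs / nfft, V = V[keep] / V[1L]),
            class = "speed_spectrum")
}

#' Spectral arc length (SPARC) movement smoothness
#'
#' Negative arc length of the normalized magnitude spectrum of the speed
#' signal over `[0, omega_c]`, where `omega_c` is the adaptive cutoff:
#' the largest frequency not exceeding `max_cutoff_hz` at which the
#' normalized magnitude still reaches `amp_threshold`. Frequencies are
#' normalized by `omega_c` before the arc length is taken, so the metric
#' is dimensionless and amplitude- and duration-scale free. Values are
#' always <= 0; a more negative SPARC means a less smooth (more
#' intermittent) movement.
#'
#' @param ss A `speed_series`, or a `speed_spectrum`.
#' @param amp_threshold Adaptive-cutoff amplitude threshold (default 0.05).
#' @param max_cutoff_hz Upper bound on the spectral band (default 20 Hz).
#' @param pad_factor Passed to [speed_spectrum()].
#' @return SPARC, a dimensionless value <= 0.
#' @export
sparc <- function(ss, amp_threshold = 0.05, max_cutoff_hz = 20,
                  pad_factor = 4) {
  spec <- if (inherits(ss, "speed_spectrum")) ss
          else speed_spectrum(ss, pad_factor = pad_factor)
  in_band <- spec$omega <= max_cutoff_hz
  om <- spec$omega[in_band]
  V <- spec$V[in_band]
  above <- which(V >= amp_threshold)
  ic <- above[length(above)]            # V[1] = 1 so this always exists
  if (ic < 2L) ic <- 2L
  om_c <- om[ic]
  sel <- seq_len(ic)
  -sum(sqrt(diff(om[sel] / om_c)^2 + diff(V[sel])^2))
}

#' Full kinematic analysis of one drawing task
#'
#' The analysis pipeline applied to every trajectory: zero-phase
#' Butterworth low-pass at `cutoff_hz`, speed from the first derivative
#' of position, RMS deviation from the ideal shape, SAT as the
#' speed/error ratio, and SPARC from the speed spectrum.
#'
#' @param traj A raw [trajectory].
#' @param ideal The matching [ideal_shape].
#' @param cutoff_hz,order Filter settings (defaults 10 Hz, order 4).
#' @param error_floor_cm SAT error floor in cm (default 0.1).
#' @param amp_threshold,max_cutoff_hz SPARC settings (defaults 0.05, 20).
#' @return List of class `kinematic_result` with `sat` (arbitrary
#'   units), `sparc` (<= 0), `mean_speed` (m/s), `error` (cm),
#'   `duration` (s).
#' @export
analyze_task <- function(traj, ideal, cutoff_hz = 10, order = 4,
                         error_floor_cm = 0.1, amp_threshold = 0.05,
                         max_cutoff_hz = 20) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("analyze_task stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  filt <- stage("filter", lowpass_filter(traj, cutoff_hz, order))
  ss <- stage("speed", speed_profile(filt))
  err <- stage("error", path_error(filt, ideal))
  sat <- stage("sat", compute_sat(filt, ideal, error_floor_cm))
  sp <- stage("sparc", sparc(ss, amp_threshold, max_cutoff_hz))
  dur <- trajectory_duration(filt)
  p <- as.matrix(filt[, c("x", "y", "z")])
  structure(list(sat = sat, sparc = sp,
                 mean_speed = sum(sqrt(rowSums(diff(p)^2))) / dur,
                 error = err, duration = dur),
            class = "kinematic_result")
}

#' @export
print.kinematic_result <- function(x, ...) {
  cat(sprintf(
    "<kinematic_result> SAT %.2f a.u., SPARC %.3f, speed %.3f m/s, error %.2f cm, %.2f s\n",
    x$sat, x$sparc, x$mean_speed, x$error, x$duration))
  invisible(x)
}
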