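# Independent oracles and fixture builders shared across the suite.

# Brute-force DFT magnitude (explicit sum, no FFT), one-sided grid
# matching speed_spectrum's layout: nfft = pad_factor * next power of 2.
dft_spectrum_oracle <- function(v, fs, pad_factor = 4) {
  n <- length(v)
  nfft <- pad_factor * 2^ceiling(log2(n))
  k <- 0:(nfft %/% 2)
  j <- 0:(n - 1)
  ang <- -2 * pi * outer(k, j) / nfft
  re <- as.vector(cos(ang) %*% v)
  im <- as.vector(sin(ang) %*% v)
  mag <- sqrt(re^2 + im^2)
  list(omega = k * fs / nfft, V = mag / mag[1L])
}

# Arc-length quadrature of a normalized spectrum under the same adaptive
# cutoff rule, accumulated in an explicit loop.
sparc_oracle <- function(v, fs, amp_threshold = 0.05, max_cutoff_hz = 20,
                         pad_factor = 4) {
  sp <- dft_spectrum_oracle(v, fs, pad_factor)
  keep <- sp$omega <= max_cutoff_hz
  om <- sp$omega[keep]; V <- sp$V[keep]
  ic <- max(which(V >= amp_threshold))
  if (ic < 2L) ic <- 2L
  total <- 0
  for (i in 2:ic) {
    total <- total +
      sqrt(((om[i] - om[i - 1]) / om[ic])^2 + (V[i] - V[i - 1])^2)
  }
  -total
}

# Analytic minimum-jerk speed profile for displacement D over [0, T].
minjerk_speed <- function(t, D, T) {
  tau <- t / T
  30 * D / T * tau^2 * (1 - tau)^2
}

# Trial-event data frame builder for regulator fixtures.
make_trials <- function(n_hit = 0, n_om = 0, n_fp = 0,
                        az_hit = 0, el_hit = 0, az_om = 0, el_om = 0,
                        az_fp = 0, el_fp = 0, fp_low = 0,
                        latency = 0.5) {
  rows <- list()
  if (n_hit) rows$hit <- data.frame(
    kind = "hit", az = rep_len(az_hit, n_hit), el = rep_len(el_hit, n_hit),
    latency = latency, salience = "none", stringsAsFactors = FALSE)
  if (n_om) rows$om <- data.frame(
    kind = "omission", az = rep_len(az_om, n_om), el = rep_len(el_om, n_om),
    latency = NA_real_, salience = "none", stringsAsFactors = FALSE)
  if (n_fp) rows$fp <- data.frame(
    kind = "false_positive", az = rep_len(az_fp, n_fp),
    el = rep_len(el_fp, n_fp), latency = NA_real_,
    salience = rep(c("low", "high"),
                   c(fp_low, n_fp - fp_low)),
    stringsAsFactors = FALSE)
  do.call(rbind, unname(rows))
}

make_block <- function(n_hit = 0, n_om = 0, n_fp = 0,
                       state = easiest_state(), block_index = 1, ...) {
  block_log(block_index, make_trials(n_hit, n_om, n_fp, ...), state)
}

# Straight uniform-motion trajectory along x with optional constant
# y-offset, for SAT/path-error closed forms.
uniform_line_traj <- function(speed = 0.3, duration = 2, offset_y = 0,
                              fs = 60) {
  t <- seq(0, duration, by = 1 / fs)
  trajectory(t, speed * t, rep(offset_y, length(t)), rep(0, length(t)),
             nominal_rate = fs, task = "line")
}

# Sinusoid-in-x trajectory for filter response checks.
sine_traj <- function(freq, amp = 0.05, duration = 10, fs = 60) {
  t <- seq(0, duration, by = 1 / fs)
  trajectory(t, amp * sin(2 * pi * freq * t), rep(0, length(t)),
             rep(0, length(t)), nominal_rate = fs)
}

# Least-squares amplitude of a sinusoid of known frequency (immune to
# the sampling-grid bias of a plain max).
sine_amplitude <- function(t, x, freq) {
  fit <- stats::lm(x ~ sin(2 * pi * freq * t) + cos(2 * pi * freq * t) - 1)
  sqrt(sum(stats::coef(fit)^2))
}

# Direct-formula one-way repeated-measures decomposition (independent of
# stats::aov) for the ANOVA fixtures.
rm_anova_oracle <- function(wide) {
  n <- nrow(wide); k <- ncol(wide)
  grand <- mean(wide)
  ss_time <- n * sum((colMeans(wide) - grand)^2)
  ss_subj <- k * sum((rowMeans(wide) - grand)^2)
  ss_tot <- sum((wide - grand)^2)
  ss_err <- ss_tot - ss_time - ss_subj
  f <- (ss_time / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  list(F = f, df = c(k - 1, (n - 1) * (k - 1)),
       p = stats::pf(f, k - 1, (n - 1) * (k - 1), lower.tail = FALSE),
       eta2 = ss_time / (ss_time + ss_err))
}

# Friedman chi-square from first principles (mid-ranks).
friedman_oracle <- function(wide) {
  n <- nrow(wide); k <- ncol(wide)
  r <- t(apply(wide, 1L, rank))
  rj <- colSums(r)
  12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
}
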