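# Shared fixtures built in code.

# A single-channel sinusoid recording.
sine_rec <- function(freq, fs = 2000, duration = 30, amp = 1, phase = 0) {
  t <- seq(0, duration, by = 1 / fs)
  recording(amp * cos(2 * pi * freq * t + phase), fs = fs)
}

# RMS amplitude of the middle portion of a channel (edges excluded).
mid_rms <- function(rec, channel = 1L, trim_s = 2) {
  x <- rec$signal[channel, ]
  i <- seq(from = trim_s * rec$fs, to = length(x) - trim_s * rec$fs)
  sqrt(mean(x[i]^2))
}

# Small fast synth config for LFP-level tests.
quick_cfg <- function(...) {
  args <- list(duration = 60, delta_amp = 50, theta_amp = 40, noise_amp = 15)
  user <- list(...)
  args[names(user)] <- user
  do.call(synth_config, args)
}

# Independent white-noise recording pair.
noise_pair <- function(duration = 120, fs = 2000, seed = 1) {
  set.seed(seed)
  n <- duration * fs
  list(recA = recording(stats::rnorm(n), fs),
       recB = recording(stats::rnorm(n), fs))
}

# von Mises sample in degrees (inversion-free: rejection sampling,
# Best & Fisher 1979) -- independent of any package code path.
rvonmises_deg <- function(n, mu_deg = 0, kappa = 1) {
  if (kappa == 0) return(stats::runif(n, -180, 180))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 0
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      i <- i + 1
      theta <- sign(u[3] - 0.5) * acos(f)
      out[i] <- theta
    }
  }
  ang <- (out * 180 / pi + mu_deg + 180) %% 360 - 180
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}
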