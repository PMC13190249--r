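#' Configuration for the synthetic two-region generator
#'
#' Bundles every generative parameter for the coupled-LFP / spike-train /
#' waveform simulator. The defaults emulate urethane-anaesthetised
#' developing cortex: a dominant slow delta oscillation, a weaker low-theta
#' (3-5 Hz) rhythm shared across regions to a tunable degree, 1/f
#' background, optional 50 Hz line noise, von Mises phase-modulated spike
#' trains and biphasic extracellular waveforms.
#'
#' @param duration recording length in seconds.
#' @param fs_raw wideband sampling rate in Hz (used for waveforms and raw
#'   synthesis; default 30000).
#' @param fs_lfp rate at which the LFP is synthesized (default 2000, the
#'   analysis rate).
#' @param delta_freq,delta_amp delta oscillation frequency (Hz) and
#'   amplitude (signal units).
#' @param theta_freq centre of the low-theta band (Hz); the theta source is
#'   narrowband noise in `theta_freq +- theta_bw/2`.
#' @param theta_amp theta SD in signal units.
#' @param theta_bw theta bandwidth in Hz (default 2, i.e. 3-5 Hz at the
#'   default centre).
#' @param coupling_c fraction of region-B theta shared with region A, in
#'   `[0, 1]`.
#' @param noise_exponent 1/f^alpha background slope, alpha >= 0.
#' @param noise_amp background SD in signal units.
#' @param line_amp 50 Hz line amplitude (0 disables).
#' @param base_rate_lambda0 mean firing rate in spikes/s.
#' @param vonmises_kappa phase-modulation concentration (0 = unmodulated).
#' @param preferred_phase_deg preferred phase in degrees, (-180, 180],
#'   0 deg = oscillation peak.
#' @param fano_shape_k gamma-renewal shape (1 = Poisson).
#' @param slow_mod_sd SD of a slow log-normal rate modulation in log units
#'   (0 disables); produces Fano factors above 1.
#' @param slow_mod_tau_s timescale of the slow modulation in seconds.
#' @param waveform_valley_to_peak_ms,waveform_fwhm_ms waveform features in
#'   ms.
#' @param waveform_snr template peak-to-peak over twice the noise SD
#'   (`Inf` = noiseless).
#' @param seed integer RNG seed; identical configurations give
#'   bit-identical output.
#' @return a validated list of class `"synth_config"`.
#' @export
synth_config <- function(duration = 120, fs_raw = 30000, fs_lfp = 2000,
                         delta_freq = 0.5, delta_amp = 100,
                         theta_freq = 4, theta_amp = 40, theta_bw = 2,
                         coupling_c = 0.3,
                         noise_exponent = 1, noise_amp = 20, line_amp = 0,
                         base_rate_lambda0 = 2, vonmises_kappa = 0,
                         preferred_phase_deg = 0, fano_shape_k = 1,
                         slow_mod_sd = 0, slow_mod_tau_s = 10,
                         waveform_valley_to_peak_ms = 0.5,
                         waveform_fwhm_ms = 0.4, waveform_snr = 20,
                         seed = 1L) {
  cfg <- list(duration = duration, fs_raw = fs_raw, fs_lfp = fs_lfp,
              delta_freq = delta_freq, delta_amp = delta_amp,
              theta_freq = theta_freq, theta_amp = theta_amp,
              theta_bw = theta_bw, coupling_c = coupling_c,
              noise_exponent = noise_exponent, noise_amp = noise_amp,
              line_amp = line_amp, base_rate_lambda0 = base_rate_lambda0,
              vonmises_kappa = vonmises_kappa,
              preferred_phase_deg = preferred_phase_deg,
              fano_shape_k = fano_shape_k, slow_mod_sd = slow_mod_sd,
              slow_mod_tau_s = slow_mod_tau_s,
              waveform_valley_to_peak_ms = waveform_valley_to_peak_ms,
              waveform_fwhm_ms = waveform_fwhm_ms,
              waveform_snr = waveform_snr, seed = as.integer(seed))
  num <- cfg[!vapply(cfg, is.character, logical(1))]
  if (!all(vapply(num, function(v) length(v) == 1 && (is.finite(v) || identical(v, Inf)), logical(1))))
    stop("synth_config: all parameters must be finite scalars (waveform_snr may be Inf)")
  if (cfg$coupling_c < 0 || cfg$coupling_c > 1)
    stop("synth_config: coupling_c must lie in [0, 1]")
  nonneg <- c("delta_amp", "theta_amp", "noise_amp", "line_amp",
              "base_rate_lambda0", "vonmises_kappa", "noise_exponent",
              "slow_mod_sd")
  for (f in nonneg) if (cfg[[f]] < 0) stop("synth_config: ", f, " must be >= 0")
  if (cfg$fano_shape_k <= 0) stop("synth_config: fano_shape_k must be > 0")
  if (cfg$duration <= 0 || cfg$fs_raw <= 0 || cfg$fs_lfp <= 0)
    stop("synth_config: duration and sampling rates must be positive")
  if (cfg$preferred_phase_deg <= -180 || cfg$preferred_phase_deg > 180)
    stop("synth_config: preferred_phase_deg must lie in (-180, 180]")
  structure(cfg, class = "synth_config")
}

# Narrowband Gaussian theta source: white noise band-passed around the
# centre frequency, scaled to unit SD. Pure tones would make coherence
# trivially 1, so the source has realistic spectral width.
theta_source <- function(n, fs, f0, bw) {
  flt <- signal::butter(2, c(f0 - bw / 2, f0 + bw / 2) / (fs / 2), type = "pass")
  x <- signal::filtfilt(flt, stats::rnorm(n))
  x / stats::sd(x)
}

# 1/f^alpha background via FFT spectral shaping of white noise.
pink_noise <- function(n, fs, alpha) {
  z <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1)) * fs / n        # avoid dividing DC by zero
  f <- pmin(f, fs - f + fs / n)             # symmetric scaling keeps x real
  x <- Re(stats::fft(z * f^(-alpha / 2), inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate a coupled two-region LFP pair
#'
#' Builds two recordings sharing a tunable fraction of a narrowband theta
#' source: region A carries theta source \eqn{s_A}; region B carries
#' \eqn{c\, s_A + \sqrt{1-c^2}\, s_B} with an independent source
#' \eqn{s_B}, renormalized so total theta power is equal in both regions
#' regardless of `coupling_c`. Each region additionally receives an
#' independent-phase delta oscillation, 1/f background, and optional 50 Hz
#' line noise (common phase).
#'
#' @param config a [synth_config()].
#' @return list with `recA`, `recB` ([recording()]s at `fs_lfp`) and
#'   `ground_truth` (the generative parameters actually used).
#' @export
generate_lfp_pair <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- as.integer(round(config$duration * config$fs_lfp))
  if (config$duration * config$theta_freq < 10)
    stop("generate_lfp_pair: need at least 10 theta cycles")
  set.seed(config$seed)
  fs <- config$fs_lfp
  tt <- seq_len(n) / fs
  c_ <- config$coupling_c
  sA <- theta_source(n, fs, config$theta_freq, config$theta_bw)
  sB <- theta_source(n, fs, config$theta_freq, config$theta_bw)
  thA <- config$theta_amp * sA
  mix <- c_ * sA + sqrt(1 - c_^2) * sB
  if (stats::sd(mix) > 0) mix <- mix / stats::sd(mix)
  thB <- config$theta_amp * mix
  mk_region <- function(theta) {
    x <- theta
    if (config$delta_amp > 0)
      x <- x + config$delta_amp * sin(2 * pi * config$delta_freq * tt +
                                        stats::runif(1, 0, 2 * pi))
    if (config$noise_amp > 0)
      x <- x + config$noise_amp * pink_noise(n, fs, config$noise_exponent)
    x
  }
  xA <- mk_region(thA)
  xB <- mk_region(thB)
  if (config$line_amp > 0) {
    ph <- stats::runif(1, 0, 2 * pi)
    line <- config$line_amp * sin(2 * pi * 50 * tt + ph)
    xA <- xA + line; xB <- xB + line
  }
  gt <- list(coupling_c = c_, theta_freq = config$theta_freq,
             theta_amp = config$theta_amp, seed = config$seed)
  list(recA = recording(xA, fs, region = "A"),
       recB = recording(xB, fs, region = "B"),
       ground_truth = gt)
}

#' Generate a phase-locked spike train from an LFP
#'
#' Inhomogeneous point process with von Mises phase modulation:
#' \deqn{\lambda(t) = \lambda_0 \exp(\kappa \cos(\theta(t) - \phi_{pref})) / I_0(\kappa)}
#' where \eqn{\theta(t)} is the instantaneous theta phase extracted with the
#' same Morlet machinery used by the locking analysis (guaranteeing phase
#' convention consistency: 0 deg = peak). Spikes are drawn by
#' time-rescaling a gamma renewal process (shape `fano_shape_k`; 1 =
#' Poisson), optionally multiplied by a slow log-normal rate modulation,
#' and a 1.5 ms dead time is imposed after each spike.
#'
#' @param lfp a [recording()] containing the theta component.
#' @param config a [synth_config()].
#' @param channel LFP channel (default 1).
#' @param unit_id identifier for the returned train.
#' @param seed optional seed; defaults to `config$seed + 1000`.
#' @return a [spike_train()]; attribute `empty_flagged` is TRUE when the
#'   expected count was below 1 and the train came out empty.
#' @export
generate_locked_spikes <- function(lfp, config, channel = 1L, unit_id = "u1",
                                   seed = NULL) {
  stopifnot(inherits(lfp, "recording"), inherits(config, "synth_config"))
  if (is.null(seed)) seed <- config$seed + 1000L
  set.seed(seed)
  fs <- lfp$fs
  dur <- rec_duration(lfp)
  ph <- morlet_phase(lfp, channel = channel, freqs = config$theta_freq)
  theta <- deg2rad(ph$phase_deg[1, ])
  kap <- config$vonmises_kappa
  phi <- deg2rad(config$preferred_phase_deg)
  lam <- config$base_rate_lambda0 *
    exp(kap * cos(theta - phi)) / besselI(kap, 0)
  if (config$slow_mod_sd > 0) {
    m <- slow_lognormal_mod(length(lam), fs, config$slow_mod_sd,
                            config$slow_mod_tau_s)
    lam <- lam * m
  }
  Lambda <- cumsum(lam) / fs
  total <- Lambda[length(Lambda)]
  k <- config$fano_shape_k
  n_draw <- max(20L, as.integer(ceiling(total + 6 * sqrt(max(total, 1)))))
  iv <- stats::rgamma(n_draw, shape = k, rate = k)
  s <- cumsum(iv)
  while (length(s) && s[length(s)] < total) {
    iv <- stats::rgamma(n_draw, shape = k, rate = k)
    s <- c(s, s[length(s)] + cumsum(iv))
  }
  s <- s[s < total]
  times <- stats::approx(c(0, Lambda), c(0, seq_along(Lambda)) / fs,
                         xout = s, ties = "ordered")$y
  times <- times[is.finite(times) & times > 0 & times < dur]
  # absolute refractoriness: 1.5 ms dead time
  if (length(times) > 1L) {
    keep <- logical(length(times)); keep[1] <- TRUE; last <- times[1]
    for (i in 2:length(times)) {
      if (times[i] - last >= 0.0015) { keep[i] <- TRUE; last <- times[i] }
    }
    times <- times[keep]
  }
  tr <- spike_train(times, duration = dur, unit_id = unit_id,
                    region = lfp$region, channel = channel)
  attr(tr, "empty_flagged") <-
    length(times) == 0 && config$base_rate_lambda0 * dur < 1
  tr
}

# Slow multiplicative log-normal rate modulation (mean 1): an
# Ornstein-Uhlenbeck-like smoothed Gaussian on the log scale.
slow_lognormal_mod <- function(n, fs, sd_log, tau_s) {
  n_slow <- max(4L, ceiling(n / (fs * tau_s / 4)))
  g <- stats::rnorm(n_slow)
  x <- stats::spline(seq(0, 1, length.out = n_slow), g, n = n)$y
  x <- x / stats::sd(x) * sd_log
  exp(x - sd_log^2 / 2)
}

#' Generate biphasic extracellular waveform templates
#'
#' Builds mean waveforms with a negative trough followed by a positive
#' rebound peak, calibrated by fixed-point iteration against the package's
#' own feature extractor so that the measured FWHM and valley-to-peak time
#' match the configured values to within one sample interval at `fs_raw`.
#' White noise scaled to `waveform_snr` (peak-to-peak over twice the noise
#' SD) is added on top of the template.
#'
#' @param config a [synth_config()].
#' @param n_units number of waveforms to generate.
#' @param seed optional seed; defaults to `config$seed + 2000`.
#' @return list of `"unit_waveform"` objects; attribute `template` on each
#'   holds the noiseless calibrated template.
#' @export
generate_waveforms <- function(config, n_units = 1L, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs_raw
  dt_ms <- 1000 / fs
  fwhm <- config$waveform_fwhm_ms
  v2p <- config$waveform_valley_to_peak_ms
  if (fwhm < 2 * dt_ms || v2p < 2 * dt_ms)
    stop("generate_waveforms: features narrower than 2 sample intervals")
  if (is.null(seed)) seed <- config$seed + 2000L
  set.seed(seed)
  tmpl <- calibrate_template(fs, fwhm, v2p)
  ptp <- max(tmpl) - min(tmpl)
  noise_sd <- if (is.infinite(config$waveform_snr)) 0 else ptp / (2 * config$waveform_snr)
  lapply(seq_len(n_units), function(i) {
    samp <- tmpl + stats::rnorm(length(tmpl), sd = noise_sd)
    wf <- unit_waveform(samp, fs = fs, unit_id = paste0("wf", i))
    attr(wf, "template") <- tmpl
    wf
  })
}

# Gaussian trough + delayed Gaussian rebound, iteratively adjusted until the
# measured features hit the configured values (superposition shifts both).
calibrate_template <- function(fs, fwhm_ms, v2p_ms, peak_frac = 0.35,
                               max_iter = 40L) {
  dt_ms <- 1000 / fs
  span_ms <- max(3, 2 * (v2p_ms + fwhm_ms) + 2)
  t_ms <- seq(0, span_ms, by = dt_ms)
  t0 <- span_ms / 3
  sig_t <- fwhm_ms / (2 * sqrt(2 * log(2)))
  sig_p <- max(v2p_ms / 2.5, 2 * dt_ms)
  d_peak <- v2p_ms
  best <- NULL; best_err <- Inf; step <- 0.8
  for (iter in seq_len(max_iter)) {
    tmpl <- -exp(-(t_ms - t0)^2 / (2 * sig_t^2)) +
      peak_frac * exp(-(t_ms - t0 - d_peak)^2 / (2 * sig_p^2))
    ft <- waveform_features(unit_waveform(tmpl, fs = fs, unit_id = "cal"))
    if (!is.finite(ft$valley_to_peak_ms) || !is.finite(ft$fwhm_ms)) {
      # overshot into a degenerate shape: back off the last update
      d_peak <- d_peak + step * (v2p_ms - d_peak)
      step <- step / 2
      next
    }
    err_v <- v2p_ms - ft$valley_to_peak_ms
    err_f <- fwhm_ms - ft$fwhm_ms
    err <- max(abs(err_v), abs(err_f))
    if (err < best_err) { best <- tmpl; best_err <- err }
    if (abs(err_v) < dt_ms / 4 && abs(err_f) < dt_ms / 4) break
    d_peak <- d_peak + step * err_v
    sig_t <- sig_t * (fwhm_ms / ft$fwhm_ms)^step
  }
  if (is.null(best)) stop("calibrate_template: could not realize the requested features")
  best
}

#' Generate a grouped cohort of synthetic recordings on disk
#'
#' Writes, for each subject of each group, a coupled region pair
#' (CSV + JSON sidecars), a spike table, and a ground-truth manifest. Group
#' effect parameters (coupling, log-rate mixture for unimodal vs bimodal
#' populations, preferred phase, concentration) override the base
#' configuration.
#'
#' @param groups list of group descriptions; each a list with `label`,
#'   `n` (subjects), and optional overrides: `coupling_c`,
#'   `preferred_phase_deg`, `vonmises_kappa`, `units_per_subject`
#'   (default 4), `log10_rate_means` (vector; two entries give a bimodal
#'   log-rate mixture), `log10_rate_sd` (default 0.2), `mixture_weights`.
#' @param base_config a [synth_config()] supplying everything not
#'   overridden.
#' @param dir output directory (created).
#' @param seed master seed for the cohort.
#' @return the manifest (also written to `manifest.json`): per-subject file
#'   paths and ground truth.
#' @export
generate_cohort <- function(groups, base_config = synth_config(), dir,
                            seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- list()
  si <- 0L
  for (g in groups) {
    if (is.null(g$n) || g$n <= 0) stop("generate_cohort: group n must be positive")
    ups <- if (is.null(g$units_per_subject)) 4L else g$units_per_subject
    means <- if (is.null(g$log10_rate_means)) log10(base_config$base_rate_lambda0) else g$log10_rate_means
    wts <- if (is.null(g$mixture_weights)) rep(1 / length(means), length(means)) else g$mixture_weights
    rsd <- if (is.null(g$log10_rate_sd)) 0.2 else g$log10_rate_sd
    for (j in seq_len(g$n)) {
      si <- si + 1L
      sub_seed <- (seed + 7919L * si) %% .Machine$integer.max
      cfg <- base_config
      cfg$seed <- as.integer(sub_seed)
      if (!is.null(g$coupling_c)) cfg$coupling_c <- g$coupling_c
      if (!is.null(g$preferred_phase_deg)) cfg$preferred_phase_deg <- g$preferred_phase_deg
      if (!is.null(g$vonmises_kappa)) cfg$vonmises_kappa <- g$vonmises_kappa
      pair <- generate_lfp_pair(cfg)
      id <- sprintf("%s_s%02d", g$label, j)
      pA <- file.path(dir, paste0(id, "_regionA.csv"))
      pB <- file.path(dir, paste0(id, "_regionB.csv"))
      write_recording(pair$recA, pA)
      write_recording(pair$recB, pB)
      set.seed(cfg$seed + 500L)
      comp <- sample.int(length(means), ups, replace = TRUE, prob = wts)
      lam <- 10^stats::rnorm(ups, mean = means[comp], sd = rsd)
      trains <- lapply(seq_len(ups), function(u) {
        ucfg <- cfg
        ucfg$base_rate_lambda0 <- lam[u]
        generate_locked_spikes(pair$recA, ucfg, unit_id = sprintf("%s_u%02d", id, u),
                               seed = cfg$seed + 600L + u)
      })
      pS <- file.path(dir, paste0(id, "_spikes.csv"))
      write_spikes(trains, pS)
      subjects[[si]] <- list(
        subject = id, group = g$label, regionA = basename(pA),
        regionB = basename(pB), spikes = basename(pS),
        ground_truth = list(coupling_c = cfg$coupling_c,
                            preferred_phase_deg = cfg$preferred_phase_deg,
                            vonmises_kappa = cfg$vonmises_kappa,
                            lambda0 = lam, seed = cfg$seed,
                            duration = cfg$duration))
    }
  }
  manifest <- list(seed = seed, n_subjects = si, subjects = subjects)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
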