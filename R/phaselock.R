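#' Instantaneous LFP phase by complex Morlet wavelet
#'
#' Convolves the LFP with complex Morlet wavelets of 4 cycles
#' (\eqn{\sigma_t = n_{cycles}/(2\pi f)}) at the analysis frequencies
#' (default 3, 3.5, 4, 4.5, 5 Hz) and returns the argument of the complex
#' coefficient in degrees. Convention: phase 0 deg at the oscillation peak,
#' +/-180 deg at the trough; the descending flank (peak to trough) spans
#' 0 deg to +180 deg.
#'
#' @param rec a conditioned [recording()] (2000 Hz typical).
#' @param channel channel index (default 1).
#' @param freqs analysis frequencies in Hz (default `seq(3, 5, by = 0.5)`).
#' @param n_cycles wavelet width in cycles (default 4).
#' @return An object of class `"phase_series"`: list with `freqs`,
#'   `phase_deg` (freqs x samples matrix in (-180, 180]), `fs`,
#'   `duration`.
#' @export
morlet_phase <- function(rec, channel = 1L, freqs = seq(3, 5, by = 0.5),
                         n_cycles = 4) {
  stopifnot(inherits(rec, "recording"))
  if (any(freqs >= rec$fs / 2)) stop("morlet_phase: frequency above Nyquist")
  x <- rec$signal[channel, ]
  dur <- rec_duration(rec)
  if (dur < 10 / min(freqs))
    stop("morlet_phase: need at least 10 cycles at the lowest frequency")
  ph <- t(vapply(freqs, function(f) {
    Arg(morlet_coef(x, rec$fs, f, n_cycles))
  }, numeric(length(x)))) * 180 / pi
  ph[ph <= -180] <- ph[ph <= -180] + 360
  structure(list(freqs = freqs, phase_deg = ph, fs = rec$fs, duration = dur),
            class = "phase_series")
}

# Complex Morlet coefficients via FFT convolution, centre-aligned.
morlet_coef <- function(x, fs, f, n_cycles) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- ceiling(4 * sigma_t * fs)
  tt <- (-half:half) / fs
  w <- exp(1i * 2 * pi * f * tt) * exp(-tt^2 / (2 * sigma_t^2))
  n <- length(x); m <- length(w)
  nfft <- stats::nextn(n + m - 1L)
  y <- stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                  stats::fft(c(w, complex(nfft - m))), inverse = TRUE) / nfft
  y[(half + 1L):(half + n)]
}

#' LFP phase at spike times
#'
#' Samples the per-frequency instantaneous phase at the nearest LFP sample
#' to each spike time. Spikes inside the edge-exclusion zone (default first
#' and last 1 s, where filter and wavelet edge effects live) are dropped and
#' counted.
#'
#' @param train a [spike_train()].
#' @param phases a `"phase_series"` from [morlet_phase()].
#' @param edge_s edge exclusion in seconds (default 1).
#' @return list with `angles` (list of numeric vectors, degrees, one per
#'   frequency), `n_used`, `n_dropped`.
#' @export
spike_phases <- function(train, phases, edge_s = 1) {
  stopifnot(inherits(train, "spike_train"), inherits(phases, "phase_series"))
  t_ok <- train$spike_times >= edge_s &
    train$spike_times <= phases$duration - edge_s
  times <- train$spike_times[t_ok]
  idx <- pmin(pmax(round(times * phases$fs) + 1L, 1L), ncol(phases$phase_deg))
  angles <- lapply(seq_along(phases$freqs), function(k) phases$phase_deg[k, idx])
  names(angles) <- paste0(phases$freqs, "Hz")
  list(angles = angles, n_used = length(idx),
       n_dropped = sum(!t_ok))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Circular mean and resultant length
#'
#' @param angles_deg angles in degrees.
#' @return `circ_mean_deg`: mean direction in (-180, 180];
#'   `resultant_length`: mean vector length in `[0, 1]`.
#' @export
circ_mean_deg <- function(angles_deg) {
  z <- mean(exp(1i * deg2rad(angles_deg)))
  ang <- rad2deg(Arg(z))
  if (ang <= -180) ang <- ang + 360
  ang
}

#' @rdname circ_mean_deg
#' @export
resultant_length <- function(angles_deg) {
  Mod(mean(exp(1i * deg2rad(angles_deg))))
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null of a uniform circular distribution against unimodal
#' concentration, with the standard finite-n approximation
#' \deqn{p = \exp(\sqrt{1 + 4n + 4(n^2 - R_n^2)} - (1 + 2n))}
#' where \eqn{R_n = n \bar R} is the resultant length of the sample.
#'
#' @param angles_deg angles in degrees; fewer than `min_n` returns `NA`
#'   (unit excluded upstream with a reason).
#' @param min_n minimum sample size (default 5).
#' @return list with `p`, `r_bar` (mean vector length), `z` (Rayleigh
#'   statistic \eqn{n \bar R^2}), `n`.
#' @export
rayleigh_test <- function(angles_deg, min_n = 5) {
  n <- length(angles_deg)
  if (n < min_n)
    return(list(p = NA_real_, r_bar = NA_real_, z = NA_real_, n = n))
  r_bar <- resultant_length(angles_deg)
  Rn <- n * r_bar
  z <- n * r_bar^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  list(p = min(p, 1), r_bar = r_bar, z = z, n = n)
}

#' Phase-locking call for one unit
#'
#' Runs a Rayleigh test per analysis frequency and calls the unit locked
#' when any Bonferroni-corrected p-value is significant (family alpha
#' divided by the number of frequencies; 0.05/5 = 0.01 at the defaults).
#' The preferred angle and resultant length are reported at the
#' minimum-p frequency, ties broken toward the lowest frequency.
#'
#' @param train a [spike_train()].
#' @param phases a `"phase_series"` from [morlet_phase()].
#' @param alpha family-wise alpha (default 0.05).
#' @param min_spikes minimum usable spikes (default 5); below this the unit
#'   is returned unlocked with `reason = "too_few_spikes"`.
#' @param edge_s edge exclusion passed to [spike_phases()].
#' @return An object of class `"unit_locking_result"`: list with `unit_id`,
#'   `freqs`, `p` (per frequency), `threshold`, `locked`, `best_freq`,
#'   `preferred_angle_deg`, `resultant_length`, `n_spikes`, `reason`.
#' @export
lock_unit <- function(train, phases, alpha = 0.05, min_spikes = 5, edge_s = 1) {
  sp <- spike_phases(train, phases, edge_s = edge_s)
  k <- length(phases$freqs)
  threshold <- alpha / k
  base <- list(unit_id = train$unit_id, freqs = phases$freqs,
               p = rep(NA_real_, k), threshold = threshold, locked = FALSE,
               best_freq = NA_real_, preferred_angle_deg = NA_real_,
               resultant_length = NA_real_, n_spikes = sp$n_used,
               reason = NA_character_)
  if (sp$n_used < min_spikes) {
    base$reason <- "too_few_spikes"
    return(structure(base, class = "unit_locking_result"))
  }
  tests <- lapply(sp$angles, rayleigh_test, min_n = min_spikes)
  base$p <- vapply(tests, `[[`, numeric(1), "p")
  best <- which.min(base$p)  # first minimum = lowest frequency on ties
  base$locked <- any(base$p < threshold, na.rm = TRUE)
  base$best_freq <- phases$freqs[best]
  base$preferred_angle_deg <- circ_mean_deg(sp$angles[[best]])
  base$resultant_length <- resultant_length(sp$angles[[best]])
  structure(base, class = "unit_locking_result")
}

#' @export
print.unit_locking_result <- function(x, ...) {
  cat(sprintf("<unit_locking_result> %s: %s (min p %.2g @ %g Hz), angle %.1f deg, R %.3f, n %d\n",
              x$unit_id, if (isTRUE(x$locked)) "LOCKED" else "not locked",
              suppressWarnings(min(x$p, na.rm = TRUE)), x$best_freq,
              x$preferred_angle_deg, x$resultant_length, x$n_spikes))
  invisible(x)
}

#' Group-level locking summary
#'
#' Counts locked units and takes the circular mean of the locked units'
#' preferred angles (the group preferred phase).
#'
#' @param results list of `"unit_locking_result"` objects.
#' @param label group label.
#' @return list with `label`, `n_locked`, `n_total`,
#'   `group_preferred_angle_deg` (`NA` when no unit is locked),
#'   `resultant_lengths` (locked units), `preferred_angles_deg` (locked
#'   units).
#' @export
group_summary <- function(results, label = "group") {
  locked <- Filter(function(r) isTRUE(r$locked), results)
  angles <- vapply(locked, `[[`, numeric(1), "preferred_angle_deg")
  list(label = label, n_locked = length(locked), n_total = length(results),
       group_preferred_angle_deg = if (length(angles)) circ_mean_deg(angles) else NA_real_,
       resultant_lengths = vapply(locked, `[[`, numeric(1), "resultant_length"),
       preferred_angles_deg = angles)
}

# Maximum-likelihood von Mises concentration from a mean resultant length
# (Fisher 1993 piecewise approximation).
kappa_from_rbar <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Watson-Williams test for equal mean directions
#'
#' Two-sample circular analogue of one-way ANOVA, with the standard
#' concentration-dependent correction factor \eqn{1 + 3/(8\hat\kappa)}.
#' The test assumes comparable, reasonably high concentrations in both
#' groups; the assumption check (pooled mean resultant length >= 0.45 and
#' group concentration ratio <= 2) is logged as a warning when violated,
#' but the test is still run.
#'
#' @param angles_a_deg,angles_b_deg angle samples in degrees, n >= 5 each.
#' @return list with `F`, `p`, `df` (numerator, denominator), `kappa`
#'   (pooled estimate), `assumption_ok`.
#' @export
watson_williams <- function(angles_a_deg, angles_b_deg) {
  if (length(angles_a_deg) < 5 || length(angles_b_deg) < 5)
    stop("watson_williams: each group needs at least 5 angles")
  groups <- list(angles_a_deg, angles_b_deg)
  n_i <- lengths(groups)
  N <- sum(n_i)
  R_i <- vapply(groups, function(g) length(g) * resultant_length(g), numeric(1))
  all_angles <- unlist(groups)
  R <- N * resultant_length(all_angles)
  rw <- sum(R_i) / N
  kappa <- kappa_from_rbar(rw)
  kap_i <- vapply(groups, function(g) kappa_from_rbar(resultant_length(g)), numeric(1))
  ratio <- max(kap_i) / max(min(kap_i), 1e-12)
  assumption_ok <- rw >= 0.45 && ratio <= 2
  if (!assumption_ok)
    warning("watson_williams: concentration assumptions violated (low or unequal kappa); interpret with caution")
  K <- 1 + 3 / (8 * kappa)
  Fstat <- K * ((N - 2) * (sum(R_i) - R)) / (N - sum(R_i))
  Fstat <- max(Fstat, 0)
  p <- stats::pf(Fstat, 1, N - 2, lower.tail = FALSE)
  list(F = Fstat, p = p, df = c(1, N - 2), kappa = kappa,
       assumption_ok = assumption_ok)
}

#' Fisher exact test on locked/non-locked counts
#'
#' Two-sided Fisher exact test comparing the proportion of locked units
#' between two groups (sum of hypergeometric probabilities of tables at
#' most as probable as the observed one).
#'
#' @param nA_locked,nA_total,nB_locked,nB_total unit counts.
#' @return list with `odds_ratio` (conditional MLE), `p`, `table`.
#' @export
locked_proportion_test <- function(nA_locked, nA_total, nB_locked, nB_total) {
  stopifnot(nA_locked >= 0, nB_locked >= 0,
            nA_locked <= nA_total, nB_locked <= nB_total)
  tab <- matrix(c(nA_locked, nA_total - nA_locked,
                  nB_locked, nB_total - nB_locked),
                nrow = 2, byrow = TRUE,
                dimnames = list(group = c("A", "B"),
                                state = c("locked", "not_locked")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}
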