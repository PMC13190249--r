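#' LFP conditioning: low-pass, downsample to 2 kHz, 50 Hz notch
#'
#' Reproduces the standard wideband-to-LFP chain: third-order Butterworth
#' low-pass below 1000 Hz, decimation to exactly 2000 Hz (integer factor),
#' and an IIR notch at the line frequency. All filtering is zero-phase
#' (forward-backward), so instantaneous phase downstream is unaffected; the
#' effective filter order is therefore doubled.
#'
#' @param rec a [recording()] with `fs >= 4000` Hz and `fs` an integer
#'   multiple of `fs_out`.
#' @param fs_out output sampling rate in Hz (default 2000).
#' @param lowpass_hz low-pass corner in Hz (default 1000).
#' @param notch_hz notch centre frequency in Hz (default 50); `NA` disables
#'   the notch.
#' @param notch_q notch quality factor (default 30).
#' @return a [recording()] at `fs_out` Hz.
#' @export
condition_lfp <- function(rec, fs_out = 2000, lowpass_hz = 1000,
                          notch_hz = 50, notch_q = 30) {
  stopifnot(inherits(rec, "recording"))
  if (rec$fs < 2 * lowpass_hz * 2)
    stop("condition_lfp: fs must be at least 4x the low-pass corner (aliasing)")
  fac <- rec$fs / fs_out
  if (abs(fac - round(fac)) > 1e-9)
    stop("condition_lfp: fs must be an integer multiple of fs_out")
  fac <- as.integer(round(fac))
  lp <- signal::butter(3, lowpass_hz / (rec$fs / 2), type = "low")
  sig <- t(apply(rec$signal, 1L, function(x) signal::filtfilt(lp, x)))
  sig <- sig[, seq(1L, ncol(sig), by = fac), drop = FALSE]
  out <- recording(sig, fs = fs_out, region = rec$region,
                   channel_meta = rec$channel_meta)
  if (!is.na(notch_hz)) out <- notch_filter(out, notch_hz, q = notch_q)
  out
}

#' Zero-phase IIR notch filter
#'
#' Second-order (biquad) notch, applied forward-backward.
#'
#' @param rec a [recording()].
#' @param f0 notch centre frequency in Hz.
#' @param q quality factor; the -3 dB bandwidth is `f0 / q`.
#' @return filtered [recording()] at the same sampling rate.
#' @export
notch_filter <- function(rec, f0, q = 30) {
  stopifnot(inherits(rec, "recording"), f0 > 0, f0 < rec$fs / 2)
  w0 <- 2 * pi * f0 / rec$fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  b <- b / a[1]; a <- a / a[1]
  sig <- t(apply(rec$signal, 1L, function(x) signal::filtfilt(b, a, x)))
  recording(sig, fs = rec$fs, region = rec$region, channel_meta = rec$channel_meta)
}

#' High-pass filter for the spike band
#'
#' Second-order Butterworth high-pass (default corner 400 Hz), zero-phase,
#' used to isolate multi-unit activity before spike detection and waveform
#' measurement. Sampling rate is unchanged.
#'
#' @param rec a [recording()] with `fs >= 2000` Hz.
#' @param corner_hz high-pass corner in Hz (default 400).
#' @return filtered [recording()].
#' @export
highpass_spikeband <- function(rec, corner_hz = 400) {
  stopifnot(inherits(rec, "recording"))
  if (rec$fs < 2000) stop("highpass_spikeband: fs must be >= 2000 Hz")
  hp <- signal::butter(2, corner_hz / (rec$fs / 2), type = "high")
  sig <- t(apply(rec$signal, 1L, function(x) signal::filtfilt(hp, x)))
  recording(sig, fs = rec$fs, region = rec$region, channel_meta = rec$channel_meta)
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass between `lo` and `hi` Hz. `lo = 0` degenerates to a
#' pure low-pass (the convention used for the 0-100 Hz band ahead of
#' coherence analysis).
#'
#' @param rec a [recording()].
#' @param lo lower band edge in Hz (`0 <= lo < hi`).
#' @param hi upper band edge in Hz (`hi < fs/2`).
#' @param order Butterworth order per pass (default 2 for band-pass, 3 when
#'   `lo = 0`).
#' @return filtered [recording()].
#' @export
bandpass <- function(rec, lo, hi, order = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (!(lo >= 0 && lo < hi && hi < rec$fs / 2))
    stop("bandpass: need 0 <= lo < hi < fs/2")
  if (lo == 0) {
    if (is.null(order)) order <- 3
    flt <- signal::butter(order, hi / (rec$fs / 2), type = "low")
  } else {
    if (is.null(order)) order <- 2
    flt <- signal::butter(order, c(lo, hi) / (rec$fs / 2), type = "pass")
  }
  sig <- t(apply(rec$signal, 1L, function(x) signal::filtfilt(flt, x)))
  recording(sig, fs = rec$fs, region = rec$region, channel_meta = rec$channel_meta)
}
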