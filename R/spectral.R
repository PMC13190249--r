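# Welch segmentation shared by PSD and coherence: returns the FFTs of
# Hamming-tapered, 50%-overlapping segments as a (nfft x n_seg) complex
# matrix, plus the taper power for density normalization.
welch_segments <- function(x, fs, window_s, overlap) {
  L <- as.integer(round(window_s * fs))
  if (L < 2) stop("welch: window shorter than 2 samples")
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  n <- length(x)
  if (n < 2L * L - step) stop("welch: signal shorter than 2 windows")
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, L - 1) / (L - 1))
  segs <- vapply(starts, function(s) x[s:(s + L - 1L)] * w, numeric(L))
  list(fft = stats::mvfft(segs), L = L, n_seg = length(starts),
       starts = starts, taper = w, u = sum(w^2))
}

one_sided <- function(L) seq_len(L %/% 2 + 1L)

#' Welch power spectral density
#'
#' PSD by Welch's method: sliding Hamming windows (default 10 s, 50%
#' overlap), periodograms averaged across windows, one-sided density
#' normalization so that integrating the PSD over frequency recovers the
#' signal variance (Parseval).
#'
#' @param rec a [recording()].
#' @param channel channel index (default 1).
#' @param window_s window length in seconds (default 10).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5).
#' @return An object of class `"psd_result"`: list with `freqs` (Hz),
#'   `power` (units^2/Hz), `window_s`, `overlap`.
#' @export
welch_psd <- function(rec, channel = 1L, window_s = 10, overlap = 0.5) {
  stopifnot(inherits(rec, "recording"))
  x <- rec$signal[channel, ]
  ws <- welch_segments(x, rec$fs, window_s, overlap)
  idx <- one_sided(ws$L)
  pxx <- rowMeans(Mod(ws$fft[idx, , drop = FALSE])^2) / (rec$fs * ws$u)
  scale2 <- rep(2, length(idx)); scale2[1] <- 1
  if (ws$L %% 2 == 0) scale2[length(idx)] <- 1
  structure(list(freqs = (idx - 1) * rec$fs / ws$L, power = pxx * scale2,
                 window_s = window_s, overlap = overlap),
            class = "psd_result")
}

#' Magnitude-squared coherence between two regions
#'
#' Welch-averaged magnitude-squared coherence
#' \deqn{C_{xy}(f) = |P_{xy}(f)|^2 / (P_{xx}(f) P_{yy}(f))}
#' computed on the 0-100 Hz band-passed signals using 3-second windows with
#' 50% overlap. Coherence from a single window is identically 1, so at least
#' two (and by default a warning below 8) windows are required.
#'
#' @param recA,recB [recording()]s of equal sampling rate and duration.
#' @param chA,chB channel indices (default 1).
#' @param window_s coherence window length in seconds (default 3).
#' @param overlap fractional overlap (default 0.5).
#' @param band_limit band-pass applied before the calculation, in Hz
#'   (default `c(0, 100)`); `NULL` disables it.
#' @param band AUC band of interest in Hz (default `c(3, 5)`, low theta).
#' @return An object of class `"coherence_result"`: list with `freqs`,
#'   `msc` in `[0,1]`, `conf_limit` (`NULL` until [shuffle_confidence()] is
#'   run), `n_windows`, `band`, `band_auc`.
#' @seealso [shuffle_confidence()], [band_auc()]
#' @export
msc <- function(recA, recB, chA = 1L, chB = 1L, window_s = 3, overlap = 0.5,
                band_limit = c(0, 100), band = c(3, 5)) {
  stopifnot(inherits(recA, "recording"), inherits(recB, "recording"))
  if (abs(recA$fs - recB$fs) > 1e-9) stop("msc: sampling rates differ")
  if (ncol(recA$signal) != ncol(recB$signal)) stop("msc: durations differ")
  if (!is.null(band_limit)) {
    recA <- bandpass(recA, band_limit[1], band_limit[2])
    recB <- bandpass(recB, band_limit[1], band_limit[2])
  }
  wa <- welch_segments(recA$signal[chA, ], recA$fs, window_s, overlap)
  wb <- welch_segments(recB$signal[chB, ], recB$fs, window_s, overlap)
  if (wa$n_seg < 2) stop("msc: needs at least 2 windows (single-window MSC is degenerate)")
  if (wa$n_seg < 8) warning("msc: fewer than 8 windows; estimates will be noisy")
  idx <- one_sided(wa$L)
  res <- msc_from_ffts(wa$fft[idx, , drop = FALSE], wb$fft[idx, , drop = FALSE])
  freqs <- (idx - 1) * recA$fs / wa$L
  out <- structure(list(freqs = freqs, msc = res, conf_limit = NULL,
                        n_windows = wa$n_seg, band = band, band_auc = NA_real_),
                   class = "coherence_result")
  out$band_auc <- band_auc(out, band[1], band[2])
  out
}

# MSC spectrum from per-window one-sided FFT matrices (freq x window).
msc_from_ffts <- function(fa, fb) {
  pxy <- rowMeans(fa * Conj(fb))
  pxx <- rowMeans(Mod(fa)^2)
  pyy <- rowMeans(Mod(fb)^2)
  val <- Mod(pxy)^2 / (pxx * pyy)
  val[!is.finite(val)] <- 0
  pmin(pmax(val, 0), 1)
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("<coherence_result> %d freqs (0-%g Hz), %d windows, band %g-%g Hz AUC %.3f%s\n",
              length(x$freqs), max(x$freqs), x$n_windows, x$band[1], x$band[2],
              x$band_auc,
              if (is.null(x$conf_limit)) "" else ", shuffle limit attached"))
  invisible(x)
}

#' Monte-Carlo shuffle confidence limit for coherence
#'
#' Surrogate null for the MSC spectrum: on each iteration every 3-second
#' region-A window is independently sample-permuted (destroying all temporal
#' structure while preserving the amplitude distribution) and the full
#' Welch MSC against the intact region-B windows is recomputed. The stated
#' quantile of the pooled surrogate distribution is returned per frequency.
#' A circular time-shift surrogate is available as a weaker alternative that
#' preserves the within-window spectrum.
#'
#' @inheritParams msc
#' @param n_iter surrogate iterations (default 100; fewer than 10 warns,
#'   fewer than 2 is an error).
#' @param quantile_p quantile of the surrogate distribution (default 0.95).
#' @param method `"permute"` (default) or `"timeshift"` (circular shift by a
#'   random offset within the window).
#' @param seed optional integer seed for reproducible surrogates.
#' @return the `coherence_result` from [msc()] with `conf_limit` filled in.
#' @export
shuffle_confidence <- function(recA, recB, chA = 1L, chB = 1L, n_iter = 100,
                               quantile_p = 0.95, window_s = 3, overlap = 0.5,
                               band_limit = c(0, 100), band = c(3, 5),
                               method = c("permute", "timeshift"), seed = NULL) {
  method <- match.arg(method)
  if (n_iter < 2) stop("shuffle_confidence: n_iter must be >= 2")
  if (n_iter < 10) warning("shuffle_confidence: n_iter < 10 gives an unstable quantile")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  out <- msc(recA, recB, chA, chB, window_s, overlap, band_limit, band)
  if (!is.null(band_limit)) {
    recA <- bandpass(recA, band_limit[1], band_limit[2])
    recB <- bandpass(recB, band_limit[1], band_limit[2])
  }
  xa <- recA$signal[chA, ]; xb <- recB$signal[chB, ]
  wa <- welch_segments(xa, recA$fs, window_s, overlap)
  idx <- one_sided(wa$L)
  # intact B-window FFTs computed once
  wb <- welch_segments(xb, recB$fs, window_s, overlap)
  fb <- wb$fft[idx, , drop = FALSE]
  L <- wa$L
  segA <- vapply(wa$starts, function(s) xa[s:(s + L - 1L)], numeric(L))
  surr <- matrix(NA_real_, nrow = n_iter, ncol = length(idx))
  for (it in seq_len(n_iter)) {
    shuf <- if (method == "permute") {
      apply(segA, 2L, function(col) col[sample.int(L)])
    } else {
      apply(segA, 2L, function(col) {
        k <- sample.int(L, 1L)
        col[c(k:L, seq_len(k - 1L))]
      })
    }
    fa <- stats::mvfft(shuf * wa$taper)[idx, , drop = FALSE]
    surr[it, ] <- msc_from_ffts(fa, fb)
  }
  out$conf_limit <- apply(surr, 2L, stats::quantile, probs = quantile_p, names = FALSE)
  out
}

#' Band area under the coherence curve
#'
#' Trapezoidal integral of the MSC spectrum over `[lo, hi]` Hz, with linear
#' interpolation of the spectrum at the band edges when they fall between
#' frequency-grid points.
#'
#' @param result a `"coherence_result"` from [msc()].
#' @param lo,hi band edges in Hz (defaults 3 and 5, the low-theta band).
#' @return dimensionless area (Hz x coherence).
#' @export
band_auc <- function(result, lo = 3, hi = 5) {
  stopifnot(inherits(result, "coherence_result"), lo < hi)
  f <- result$freqs; y <- result$msc
  if (lo < min(f) || hi > max(f)) stop("band_auc: band outside frequency range")
  inside <- f > lo & f < hi
  fg <- c(lo, f[inside], hi)
  yg <- c(stats::approx(f, y, xout = lo)$y, y[inside],
          stats::approx(f, y, xout = hi)$y)
  pracma::trapz(fg, yg)
}

#' Fold change in band coherence between two age groups
#'
#' Cross-sectional fold change: each older-animal band AUC is divided by the
#' mean AUC of the younger group, and the fold values are summarized as
#' median (IQR). Zero or negative AUCs are rejected.
#'
#' @param auc_young numeric vector of per-animal AUCs in the younger group.
#' @param auc_old numeric vector of per-animal AUCs in the older group.
#' @return list with `folds` (per older animal), `median`, `iqr`
#'   (Q3 - Q1, linear-interpolation quantiles), and group sizes.
#' @export
fold_change <- function(auc_young, auc_old) {
  if (!length(auc_young) || !length(auc_old))
    stop("fold_change: both groups must be non-empty")
  if (any(auc_young <= 0) || any(auc_old <= 0))
    stop("fold_change: AUC values must be positive")
  folds <- auc_old / mean(auc_young)
  qs <- stats::quantile(folds, c(0.25, 0.5, 0.75), names = FALSE)
  list(folds = folds, median = qs[2], iqr = qs[3] - qs[1],
       n_young = length(auc_young), n_old = length(auc_old))
}
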