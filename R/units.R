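#' Mean single-unit spike waveform
#'
#' @param samples numeric vector, mean waveform in signal units; must
#'   contain a unique global minimum (the trough) and span at least 2 ms.
#' @param fs sampling rate in Hz.
#' @param unit_id identifier.
#' @return object of class `"unit_waveform"`: list with `samples`, `fs`,
#'   `unit_id`, `alignment` (trough sample index).
#' @export
unit_waveform <- function(samples, fs, unit_id = "u1") {
  samples <- as.numeric(samples)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("unit_waveform: non-finite samples")
  if (length(samples) < 2e-3 * fs)
    stop("unit_waveform: waveform must span at least 2 ms")
  trough <- which(samples == min(samples))
  if (length(trough) != 1L)
    stop("unit_waveform: waveform must have a unique global minimum")
  structure(list(samples = samples, fs = fs, unit_id = unit_id,
                 alignment = trough),
            class = "unit_waveform")
}

#' Firing rate and Fano factor
#'
#' Mean rate is total spikes over duration. The Fano factor is the
#' variance-to-mean ratio of spike counts in non-overlapping bins
#' (default 1 s): 1 for a Poisson process, below 1 for regular firing,
#' above 1 for bursty or slowly modulated firing.
#'
#' @param train a [spike_train()] with duration at least `10 * bin_s`.
#' @param bin_s count bin width in seconds (default 1).
#' @param origin_s bin origin offset in seconds (default 0); partial bins
#'   at either end are discarded.
#' @return list with `mean_rate` (spikes/s), `fano` (`NA` with
#'   `fano_defined = FALSE` for an empty train), `n_spikes`, `n_bins`.
#' @export
firing_metrics <- function(train, bin_s = 1.0, origin_s = 0) {
  stopifnot(inherits(train, "spike_train"))
  if (train$duration < 10 * bin_s)
    stop("firing_metrics: duration must be at least 10 bins")
  n <- length(train$spike_times)
  rate <- n / train$duration
  edges <- seq(origin_s, train$duration, by = bin_s)
  if (length(edges) < 3) stop("firing_metrics: fewer than 2 complete bins")
  inside <- train$spike_times >= edges[1] &
    train$spike_times < edges[length(edges)]
  counts <- graphics::hist(train$spike_times[inside], breaks = edges,
                           plot = FALSE, right = FALSE)$counts
  if (n == 0)
    return(list(mean_rate = 0, fano = NA_real_, fano_defined = FALSE,
                n_spikes = 0L, n_bins = length(counts)))
  list(mean_rate = rate,
       fano = stats::var(counts) / mean(counts),
       fano_defined = TRUE, n_spikes = n, n_bins = length(counts))
}

# Parabolic (three-point) sub-sample interpolation of an extremum.
# Returns offset in samples relative to i and the interpolated value.
parabolic_refine <- function(y, i) {
  if (i <= 1L || i >= length(y))
    return(list(offset = 0, value = y[i]))
  d <- (y[i - 1] - y[i + 1]) / (2 * (y[i - 1] - 2 * y[i] + y[i + 1]))
  if (!is.finite(d) || abs(d) > 1) d <- 0
  val <- y[i] - 0.25 * (y[i - 1] - y[i + 1]) * d
  list(offset = d, value = val)
}

#' Waveform features: valley-to-peak time and FWHM
#'
#' Valley-to-peak is the time from the global trough to the subsequent
#' positive maximum (within 2 ms), a proxy for the medium
#' afterhyperpolarization duration. FWHM is the full width of the trough at
#' half its depth relative to a baseline taken as the median of the
#' pre-trough samples. Both use parabolic sub-sample interpolation at the
#' extrema and linear interpolation at the half-depth crossings.
#'
#' @param wf a [unit_waveform()].
#' @param max_peak_ms search window for the rebound peak after the trough
#'   (default 2 ms).
#' @return list with `valley_to_peak_ms`, `fwhm_ms`, `defined`, `reason`
#'   (`NA` or why a feature is undefined).
#' @export
waveform_features <- function(wf, max_peak_ms = 2) {
  stopifnot(inherits(wf, "unit_waveform"))
  y <- wf$samples; fs <- wf$fs
  ti <- wf$alignment
  baseline <- if (ti > 1L) stats::median(y[seq_len(ti - 1L)]) else 0
  tr <- parabolic_refine(y, ti)
  trough_pos <- ti + tr$offset
  depth <- baseline - tr$value
  out <- list(valley_to_peak_ms = NA_real_, fwhm_ms = NA_real_,
              defined = FALSE, reason = NA_character_)
  if (depth <= 0) { out$reason <- "no_trough_depth"; return(out) }
  # rebound peak within the search window after the trough
  hi <- min(length(y), ti + as.integer(round(max_peak_ms * fs / 1000)))
  if (hi <= ti + 1L) { out$reason <- "no_post_trough_window"; return(out) }
  seg <- y[(ti + 1L):hi]
  pk_rel <- which.max(seg)
  pk <- ti + pk_rel
  if (pk >= hi || seg[pk_rel] <= baseline) {
    out$reason <- "no_rebound_peak"; return(out)
  }
  pkref <- parabolic_refine(y, pk)
  out$valley_to_peak_ms <- (pk + pkref$offset - trough_pos) / fs * 1000
  # half-depth crossings around the trough
  level <- baseline - depth / 2
  li <- ti
  while (li > 1L && y[li] < level) li <- li - 1L
  ri <- ti
  while (ri < length(y) && y[ri] < level) ri <- ri + 1L
  if (y[li] < level || y[ri] < level) { out$reason <- "trough_unbounded"; return(out) }
  xl <- li + (level - y[li]) / (y[li + 1L] - y[li])
  xr <- (ri - 1L) + (level - y[ri - 1L]) / (y[ri] - y[ri - 1L])
  out$fwhm_ms <- (xr - xl) / fs * 1000
  out$defined <- TRUE
  out
}

#' Regular-spiking vs fast-spiking classification
#'
#' A unit is called fast-spiking (putative inhibitory) when both waveform
#' features fall strictly below 0.3 ms (half-width and valley-to-peak);
#' otherwise it is regular-spiking (putative excitatory). Boundary values
#' classify as regular-spiking.
#'
#' @param valley_to_peak_ms,fwhm_ms waveform features in ms.
#' @param threshold_ms classification threshold (default 0.3).
#' @return `"fast_spiking"` or `"regular_spiking"`.
#' @export
classify_unit <- function(valley_to_peak_ms, fwhm_ms, threshold_ms = 0.3) {
  if (!is.finite(valley_to_peak_ms) || !is.finite(fwhm_ms))
    stop("classify_unit: both features must be defined")
  if (fwhm_ms < threshold_ms && valley_to_peak_ms < threshold_ms)
    "fast_spiking" else "regular_spiking"
}

#' Cluster separation quality: Isolation Distance and L-ratio
#'
#' Mahalanobis-based separation of one unit's cluster from all other
#' events in a feature space. Isolation Distance is the squared Mahalanobis
#' distance (from the cluster centre, using the cluster covariance) of the
#' n-th closest non-cluster event, n the cluster size. The L-ratio is
#' \eqn{\sum_{noise} (1 - F_{\chi^2_d}(D^2)) / n}.
#'
#' @param features numeric matrix, events x feature dimensions.
#' @param labels cluster label per event.
#' @param unit label of the unit of interest.
#' @return list with `isolation_distance` (`Inf` when fewer noise events
#'   than cluster events), `l_ratio`, `n_cluster`, `n_noise`.
#' @export
cluster_quality <- function(features, labels, unit) {
  features <- as.matrix(features)
  inx <- labels == unit
  n_u <- sum(inx); n_o <- sum(!inx)
  if (n_u < ncol(features) + 1)
    stop("cluster_quality: cluster too small for covariance estimate")
  mu <- colMeans(features[inx, , drop = FALSE])
  S <- stats::cov(features[inx, , drop = FALSE])
  d2 <- stats::mahalanobis(features[!inx, , drop = FALSE], mu, S)
  l <- sum(stats::pchisq(d2, df = ncol(features), lower.tail = FALSE)) / n_u
  id <- if (n_o >= n_u) sort(d2)[n_u] else Inf
  list(isolation_distance = id, l_ratio = l, n_cluster = n_u, n_noise = n_o)
}

#' Fraction of inter-spike intervals violating the refractory period
#'
#' @param train a [spike_train()].
#' @param refractory_ms refractory period in ms (default 1).
#' @return fraction of ISIs shorter than `refractory_ms`.
#' @export
isi_violation_fraction <- function(train, refractory_ms = 1) {
  stopifnot(inherits(train, "spike_train"))
  isi <- diff(train$spike_times)
  if (!length(isi)) return(0)
  mean(isi < refractory_ms / 1000)
}

#' Waveform signal-to-noise ratio
#'
#' Peak-to-peak amplitude of the mean waveform divided by twice the SD of
#' the residual noise (individual spikes minus the mean).
#'
#' @param mean_wf numeric vector, mean waveform.
#' @param residual_sd SD of the residual noise in the same units.
#' @return dimensionless SNR.
#' @export
waveform_snr <- function(mean_wf, residual_sd) {
  (max(mean_wf) - min(mean_wf)) / (2 * residual_sd)
}

#' Quality-control filter for sorted units
#'
#' Applies the acceptance rules: SNR at least the source-specific threshold
#' (5 for OpenEphys, 11 for Neuralynx acquisitions), Isolation Distance
#' above 25, L-ratio below 0.5, and no inter-spike intervals shorter than
#' the 1 ms refractory period (tolerance configurable, default 0). Units
#' missing any QC field are rejected with reason "unscored".
#'
#' @param units list; each element needs a `qc` list with `snr`,
#'   `isolation_distance`, `l_ratio`, `isi_violation_fraction`.
#' @param source `"openephys"` or `"neuralynx"` (sets the SNR threshold).
#' @param isi_tolerance maximum tolerated ISI-violation fraction
#'   (default 0).
#' @param min_isolation,max_l_ratio separation thresholds (defaults 25 and
#'   0.5).
#' @return list with `accepted` (the surviving units) and `log`
#'   (data.frame: unit_id, accepted, reason).
#' @export
qc_filter <- function(units, source = c("openephys", "neuralynx"),
                      isi_tolerance = 0, min_isolation = 25,
                      max_l_ratio = 0.5) {
  source <- match.arg(source)
  snr_min <- switch(source, openephys = 5, neuralynx = 11)
  need <- c("snr", "isolation_distance", "l_ratio", "isi_violation_fraction")
  rows <- lapply(seq_along(units), function(i) {
    u <- units[[i]]
    id <- if (!is.null(u$unit_id)) u$unit_id else paste0("unit", i)
    qc <- u$qc
    if (is.null(qc) || !all(need %in% names(qc)) ||
        any(!vapply(qc[need], function(v) length(v) == 1 && is.finite(v) || identical(v, Inf), logical(1))))
      return(data.frame(unit_id = id, accepted = FALSE, reason = "unscored"))
    reason <- NA_character_
    if (qc$snr < snr_min) reason <- sprintf("snr_below_%g", snr_min)
    else if (!(qc$isolation_distance > min_isolation)) reason <- "isolation_distance"
    else if (!(qc$l_ratio < max_l_ratio)) reason <- "l_ratio"
    else if (qc$isi_violation_fraction > isi_tolerance) reason <- "isi_violations"
    data.frame(unit_id = id, accepted = is.na(reason),
               reason = ifelse(is.na(reason), "accepted", reason))
  })
  log <- do.call(rbind, rows)
  list(accepted = units[log$accepted], log = log)
}

#' Detect spikes on the high-passed band by amplitude threshold
#'
#' Negative-going threshold at `k` times a robust (MAD-based) noise SD;
#' each detection is the local minimum of a threshold crossing, with a 1 ms
#' dead time.
#'
#' @param rec a high-passed [recording()] (see [highpass_spikeband()]).
#' @param channel channel index.
#' @param k threshold in noise SDs (default 4).
#' @param dead_time_ms minimum separation between detections (default 1).
#' @return a [spike_train()].
#' @export
detect_spikes <- function(rec, channel = 1L, k = 4, dead_time_ms = 1) {
  stopifnot(inherits(rec, "recording"))
  x <- rec$signal[channel, ]
  noise_sd <- stats::mad(x)
  thr <- -k * noise_sd
  below <- x < thr
  if (!any(below)) return(spike_train(numeric(), rec_duration(rec),
                                      unit_id = "det", region = rec$region,
                                      channel = channel))
  runs <- rle(below)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  mins <- mapply(function(s, e) s - 1L + which.min(x[s:e]),
                 starts[runs$values], ends[runs$values])
  times <- sort(mins) / rec$fs
  keep <- c(TRUE, diff(times) >= dead_time_ms / 1000)
  spike_train(times[keep], rec_duration(rec), unit_id = "det",
              region = rec$region, channel = channel)
}

#' Logarithmic firing-rate histogram
#'
#' Histogram of log10 firing rates in fixed-width bins (default 0.3
#' log10 units), with the left edge at the floor of the minimum in bin
#' units. Zero or negative rates are excluded and counted.
#'
#' @param rates firing rates in spikes/s.
#' @param bin_width bin width in log10 units (default 0.3).
#' @return list with `breaks`, `mids`, `counts` (log10-rate axis),
#'   `n_excluded`.
#' @export
log_rate_histogram <- function(rates, bin_width = 0.3) {
  bad <- !(is.finite(rates) & rates > 0)
  lr <- log10(rates[!bad])
  if (!length(lr)) stop("log_rate_histogram: no positive rates")
  lo <- floor(min(lr) / bin_width) * bin_width
  hi <- ceiling(max(lr) / bin_width + 1e-9) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(lr, breaks = breaks, plot = FALSE, right = FALSE,
                      include.lowest = TRUE)
  list(breaks = h$breaks, mids = h$mids, counts = h$counts,
       n_excluded = sum(bad))
}

#' Rank correlation between firing rate and spike half-width
#'
#' Spearman correlation across units; used to check for the absence of a
#' rate/half-width anti-correlation.
#'
#' @param mean_rate firing rates (spikes/s).
#' @param fwhm_ms half-widths (ms); pairs with undefined values are
#'   dropped.
#' @return list with `rho`, `p`, `n`, `defined` (`FALSE` when either
#'   variable is constant).
#' @export
rate_width_correlation <- function(mean_rate, fwhm_ms) {
  ok <- is.finite(mean_rate) & is.finite(fwhm_ms)
  x <- mean_rate[ok]; y <- fwhm_ms[ok]
  if (length(x) < 5) stop("rate_width_correlation: need at least 5 units")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(x), defined = FALSE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
       defined = TRUE)
}
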