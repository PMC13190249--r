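#' Continuous multi-channel recording
#'
#' Lightweight container for a block of continuous extracellular signal from
#' one region: a channels x samples matrix plus sampling rate and per-channel
#' metadata. All LFP-level analyses in the package consume this object.
#'
#' @param signal numeric matrix, channels x samples (a vector is treated as a
#'   single channel), in arbitrary signal units.
#' @param fs sampling rate in Hz.
#' @param region region label (e.g. "PL", "IL", "BLAa", or a synthetic label).
#' @param channel_meta optional data.frame with one row per channel
#'   (columns such as layer, subject, group, sex, age_class). A minimal
#'   data.frame is built when omitted.
#' @return An object of class `"recording"`: a list with elements `signal`,
#'   `fs`, `region`, `channel_meta`.
#' @examples
#' rec <- recording(sin(2 * pi * 4 * seq(0, 10, by = 1 / 2000)), fs = 2000)
#' rec
#' @export
recording <- function(signal, fs, region = "synthetic", channel_meta = NULL) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1L)
  stopifnot(is.matrix(signal), is.numeric(signal))
  if (!all(is.finite(signal))) stop("recording: signal contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("recording: fs must be a single positive number")
  n_ch <- nrow(signal)
  if (is.null(channel_meta)) {
    channel_meta <- data.frame(channel = seq_len(n_ch), region = region,
                               stringsAsFactors = FALSE)
  }
  if (nrow(channel_meta) != n_ch)
    stop("recording: channel_meta must have one row per channel")
  structure(list(signal = signal, fs = as.numeric(fs), region = region,
                 channel_meta = channel_meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s), %d samples @ %g Hz (%.1f s), region %s\n",
              nrow(x$signal), ncol(x$signal), x$fs,
              ncol(x$signal) / x$fs, x$region))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a [recording()].
#' @return duration in seconds.
#' @export
rec_duration <- function(rec) ncol(rec$signal) / rec$fs

#' Single-unit spike train
#'
#' Spike timestamps for one sorted unit, tied to the recording they came
#' from. Times must be sorted, strictly inside `[0, duration]`, and free of
#' duplicates closer than 0.1 ms.
#'
#' @param spike_times numeric vector of spike times in seconds.
#' @param duration recording duration in seconds.
#' @param unit_id unit identifier.
#' @param region region label.
#' @param channel channel of origin.
#' @return An object of class `"spike_train"`.
#' @export
spike_train <- function(spike_times, duration, unit_id = "u1",
                        region = "synthetic", channel = 1L) {
  spike_times <- as.numeric(spike_times)
  if (anyNA(spike_times) || any(!is.finite(spike_times)))
    stop("spike_train: non-finite spike times")
  if (is.unsorted(spike_times)) stop("spike_train: spike times must be sorted")
  if (length(spike_times) && (spike_times[1] < 0 || spike_times[length(spike_times)] > duration))
    stop("spike_train: spike times outside [0, duration]")
  if (length(spike_times) > 1L && any(diff(spike_times) < 1e-4))
    stop("spike_train: duplicate spikes closer than 0.1 ms")
  structure(list(unit_id = unit_id, spike_times = spike_times,
                 duration = as.numeric(duration), region = region,
                 channel = channel),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> unit %s: %d spikes over %.1f s (%.2f Hz), region %s\n",
              x$unit_id, length(x$spike_times), x$duration,
              length(x$spike_times) / x$duration, x$region))
  invisible(x)
}

#' Write / read a recording as CSV signal + JSON metadata sidecar
#'
#' Continuous signals are stored as a plain CSV (one column per channel) with
#' a `<path>.json` sidecar carrying sampling rate, region and channel
#' metadata, so datasets remain text and diffable.
#'
#' @param rec a [recording()].
#' @param path CSV file path; the sidecar goes to `paste0(path, ".json")`.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a [recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  m <- t(rec$signal)
  colnames(m) <- paste0("ch", seq_len(ncol(m)))
  utils::write.csv(m, path, row.names = FALSE)
  meta <- list(fs = rec$fs, region = rec$region, channel_meta = rec$channel_meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  m <- as.matrix(utils::read.csv(path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  recording(t(m), fs = meta$fs, region = meta$region,
            channel_meta = as.data.frame(meta$channel_meta))
}

#' Write / read spike tables (unit_id, spike_time_s, channel, region)
#'
#' @param trains list of [spike_train()] objects.
#' @param path CSV file path.
#' @param duration recording duration in seconds (stored per file by the
#'   caller; required when reading).
#' @return `write_spikes` returns `path` invisibly; `read_spikes` a list of
#'   [spike_train()].
#' @export
write_spikes <- function(trains, path) {
  rows <- do.call(rbind, lapply(trains, function(tr) {
    if (!length(tr$spike_times)) return(NULL)
    data.frame(unit_id = tr$unit_id, spike_time_s = tr$spike_times,
               channel = tr$channel, region = tr$region,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(unit_id = character(), spike_time_s = numeric(),
                       channel = integer(), region = character())
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path, duration) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(df$unit_id)
  lapply(ids, function(id) {
    sub <- df[df$unit_id == id, , drop = FALSE]
    spike_train(sort(sub$spike_time_s), duration = duration, unit_id = id,
                region = sub$region[1], channel = sub$channel[1])
  })
}
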