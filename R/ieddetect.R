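#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (zero-phase); an optional notch removes mains interference. The applied
#' band is recorded in the recording metadata.
#'
#' @param rec an `irritmap_recording`.
#' @param low_hz,high_hz band edges, Hz (0 < low < high < Nyquist).
#' @param notch_hz optional notch center frequency, Hz.
#' @param order filter order (of the underlying one-pass design).
#' @return The filtered `irritmap_recording`.
#' @export
bandpass <- function(rec, low_hz, high_hz, notch_hz = NULL, order = 4) {
  stopifnot(inherits(rec, "irritmap_recording"))
  nyq <- rec$sampling_rate / 2
  if (!(0 < low_hz && low_hz < high_hz && high_hz < nyq)) {
    stop_irritmap("Band edges must satisfy 0 < low < high < Nyquist.",
                  "irritmap_filter_error")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- t(apply(rec$data, 1L, function(x) signal::filtfilt(bf, x)))
  if (!is.null(notch_hz)) {
    if (notch_hz >= nyq) {
      stop_irritmap("Notch frequency must be below Nyquist.",
                    "irritmap_filter_error")
    }
    nf <- signal::butter(2, c(notch_hz - 2, notch_hz + 2) / nyq,
                         type = "stop")
    out <- t(apply(out, 1L, function(x) signal::filtfilt(nf, x)))
  }
  new_recording(out, rec$sampling_rate, channels = rec$channels,
                referenced = rec$referenced, band = c(low_hz, high_hz))
}

# Gaussian smoothing of a vector (zero-phase, reflected edges).
gauss_smooth <- function(x, sigma_samples) {
  if (sigma_samples <= 0) return(x)
  half <- ceiling(4 * sigma_samples)
  k <- exp(-(-half:half)^2 / (2 * sigma_samples^2))
  k <- k / sum(k)
  xp <- c(rev(x[seq_len(half)]), x, rev(x[length(x) - seq_len(half) + 1L]))
  as.vector(stats::filter(xp, k, sides = 2))[(half + 1L):(half + length(x))]
}

# Robust per-channel scale: 1.4826 x MAD, falling back to the SD for traces
# that are zero more than half the time (e.g., noiseless simulations).
robust_scale <- function(x) {
  s <- mad(x)
  if (s <= 0) s <- sd(x)
  s
}

# Multichannel transient envelope: per-channel robust standardization, then
# the square root of the baseline-corrected mean square across channels.
# For a discharge s(t) projected over the montage this is proportional to
# |s(t)|, so its FWHM equals the waveform's FWHM, while channel-independent
# background averages out.
# signed, smoothed excess of the across-channel mean square over its
# running-median baseline (the multichannel power excursion)
pooled_excess <- function(rec, smooth_sigma_ms = 10, baseline_s = 1.5) {
  med <- apply(rec$data, 1L, median)
  rob <- apply(rec$data, 1L, robust_scale)
  ok <- rob > 0
  z <- (rec$data[ok, , drop = FALSE] - med[ok]) / rob[ok]
  ms <- colMeans(z^2)
  # running-median baseline: tracks slow background power without being
  # pulled up by brief (sub-second) discharges
  k <- min(2L * floor(baseline_s * rec$sampling_rate / 2) + 1L,
           2L * floor((length(ms) - 1L) / 2) + 1L)
  base <- if (k >= 3) stats::runmed(ms, k, endrule = "median") else median(ms)
  gauss_smooth(ms - base, smooth_sigma_ms / 1000 * rec$sampling_rate)
}

pooled_envelope <- function(rec, smooth_sigma_ms = 10, baseline_s = 1.5) {
  d <- pooled_excess(rec, smooth_sigma_ms = 0, baseline_s = baseline_s)
  gauss_smooth(sqrt(pmax(d, 0)),
               smooth_sigma_ms / 1000 * rec$sampling_rate)
}

# FWHM (ms) of the envelope around `peak`; returns NA when no half-maximum
# crossing exists inside the trace. The peak is refined on the lightly
# smoothed envelope `env_peak` (heavier smoothing shifts the mode of
# asymmetric waveforms); the width is walked on `env`, whose smoothing
# kernel is then removed in quadrature (Gaussian deconvolution).
measure_fwhm <- function(env, env_peak, peak, fs, smooth_sigma_ms = 10) {
  if (!is.finite(peak) || peak < 1L || peak > length(env)) {
    return(list(fwhm = NA_real_, peak = peak))
  }
  win <- max(1L, peak - round(0.06 * fs)):min(length(env),
                                              peak + round(0.06 * fs))
  win <- win[is.finite(env_peak[win])]
  if (!length(win)) return(list(fwhm = NA_real_, peak = peak))
  peak <- win[which.max(env_peak[win])]
  half <- max(env[max(1L, peak - 2L):min(length(env), peak + 2L)]) / 2
  if (half <= 0) return(list(fwhm = NA_real_, peak = peak))
  left <- peak
  while (left > 1L && env[left - 1L] >= half) left <- left - 1L
  right <- peak
  while (right < length(env) && env[right + 1L] >= half) right <- right + 1L
  if (left == 1L || right == length(env)) return(list(fwhm = NA_real_,
                                                      peak = peak))
  # linear interpolation to the half-maximum crossings
  fl <- left - (env[left] - half) / (env[left] - env[left - 1L])
  fr <- right + (env[right] - half) / (env[right] - env[right + 1L])
  raw <- (fr - fl) / fs * 1000
  kern <- 2 * sqrt(2 * log(2)) * smooth_sigma_ms
  list(fwhm = sqrt(max(raw^2 - kern^2, 1e-6)), peak = peak)
}

#' Threshold-based IED detection
#'
#' Detects transient events on a (band-filtered) recording. Each channel is
#' robust-standardized (deviation from the channel median in units of
#' 1.4826 x MAD); the detection statistic is the across-channel mean square
#' of the standardized channels, corrected by a running-median baseline and
#' lightly smoothed — it pools the discharge's coherent multichannel
#' projection while channel-independent background noise averages out. The
#' statistic is thresholded at its median plus `k_sd` robust standard
#' deviations; threshold-crossing runs yield candidate peaks, candidates
#' within the refractory window are merged keeping the largest, and events
#' supported by fewer than `min_channels` channels (|z| above half the
#' threshold near the peak) are rejected. Peak times are refined on — and
#' events must also pass the same `k_sd` threshold on — the measurement
#' recording `duration_rec` (the broadband recording, when supplied).
#' Event duration is the FWHM of the multichannel envelope of
#' `duration_rec`, with the smoothing kernel removed in quadrature; events
#' with durations outside \[20, 200\] ms are discarded. Durations in
#' \[20, 70) ms classify as spikes, \[70, 200\] ms as sharp-waves.
#'
#' @param rec a band-filtered `irritmap_recording`.
#' @param k_sd threshold in robust SD units (default 4).
#' @param refractory_ms merge window between candidate peaks.
#' @param min_channels minimum supporting channels per event.
#' @param duration_rec recording on which durations and final peak times are
#'   measured (default: `rec` itself).
#' @return An event tibble with columns `peak_sample`, `peak_s`, `channel`,
#'   `amp_uV`, `duration_ms`, `kind`, sorted by time.
#' @export
detect_events <- function(rec, k_sd = 4, refractory_ms = 300,
                          min_channels = 2, duration_rec = NULL) {
  stopifnot(inherits(rec, "irritmap_recording"))
  fs <- rec$sampling_rate
  if (is.null(duration_rec)) duration_rec <- rec
  nt <- ncol(rec$data)
  med <- apply(rec$data, 1L, median)
  rob <- apply(rec$data, 1L, robust_scale)
  usable <- rob > 0
  if (!any(usable)) return(empty_events())
  if (!all(usable)) {
    warn(sprintf("Excluding %d flat channel(s) from detection.",
                 sum(!usable)))
  }
  z <- abs((rec$data - med) / ifelse(usable, rob, Inf))
  gfp <- pooled_excess(rec)
  thr <- median(gfp) + k_sd * robust_scale(gfp)
  over <- gfp > thr
  if (!any(over)) return(empty_events())

  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  cand <- vapply(runs, function(i) {
    seg <- starts[i]:ends[i]
    seg[which.max(gfp[seg])]
  }, integer(1))
  cand <- cand[order(-gfp[cand])]

  refr <- round(refractory_ms / 1000 * fs)
  accepted <- integer(0)
  for (p in cand) {
    if (length(accepted) && min(abs(accepted - p)) <= refr) next
    accepted <- c(accepted, p)
  }

  env <- pooled_envelope(duration_rec)
  env_light <- pooled_envelope(duration_rec, smooth_sigma_ms = 0)
  same_rec <- identical(duration_rec, rec)
  dmeas <- if (same_rec) gfp else pooled_excess(duration_rec)
  thr_meas <- median(dmeas) + k_sd * robust_scale(dmeas)
  rows <- list()
  supp_win <- round(0.03 * fs)
  for (p in accepted) {
    win <- max(1L, p - supp_win):min(nt, p + supp_win)
    zwin <- z[, win, drop = FALSE]
    support <- sum(apply(zwin >= k_sd / 2, 1L, any) & usable)
    if (support < min_channels) next
    ch <- which.max(apply(zwin, 1L, max) * usable)
    fw <- measure_fwhm(env, env_light, p, fs)
    if (is.na(fw$fwhm) || fw$fwhm < 20 || fw$fwhm > 200) next
    # the discharge must also stand out on the measurement recording itself
    if (fw$peak >= 1L && fw$peak <= length(dmeas) &&
        dmeas[fw$peak] <= thr_meas) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      peak_sample = fw$peak,
      channel = rec$channels[ch],
      amp_uV = duration_rec$data[ch, fw$peak],
      duration_ms = fw$fwhm)
  }
  if (!length(rows)) return(empty_events())
  out <- dplyr::bind_rows(rows)
  out <- out[!duplicated(out$peak_sample), ]
  # refined peaks can collapse distinct candidates onto the same discharge;
  # merge again within the refractory window, keeping the largest envelope
  out <- out[order(-env[out$peak_sample]), ]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    close_by <- abs(out$peak_sample - out$peak_sample[i]) <= refr
    close_by[i] <- FALSE
    keep[close_by] <- FALSE
  }
  out <- out[keep, ]
  out$peak_s <- (out$peak_sample - 1L) / fs
  out$kind <- ifelse(out$duration_ms < 70, "spike", "sharp_wave")
  dplyr::arrange(
    dplyr::select(out, "peak_sample", "peak_s", "channel", "amp_uV",
                  "duration_ms", "kind"),
    .data$peak_sample)
}

empty_events <- function() {
  tibble::tibble(peak_sample = integer(0), peak_s = numeric(0),
                 channel = character(0), amp_uV = numeric(0),
                 duration_ms = numeric(0), kind = character(0))
}

#' Detect IEDs on the spike, sharp-wave and broadband streams
#'
#' Runs [detect_events()] on the 15-50 Hz (spike) and 5-15 Hz (sharp-wave)
#' band-filtered streams of a broadband recording and, by default, on the
#' broadband recording itself (the thresholded trace in the source
#' methodology is the unfiltered scalp EEG; the band streams separate the
#' waveform kinds). Duplicate detections across streams (peaks within
#' `dedup_ms`) are resolved in favor of the spike stream, then the
#' sharp-wave stream. Durations — and hence the spike/sharp-wave kind — and
#' final peak times are always measured on the broadband recording.
#'
#' @param rec broadband `irritmap_recording`.
#' @param k_sd,refractory_ms,min_channels passed to [detect_events()].
#' @param spike_band,sw_band stream band edges, Hz.
#' @param include_broadband also detect on the unfiltered recording.
#' @param dedup_ms cross-stream duplicate window, ms.
#' @param notch_hz optional mains notch applied to both band streams.
#' @return An event tibble (see [detect_events()]).
#' @export
detect_ieds <- function(rec, k_sd = 4, refractory_ms = 300, min_channels = 2,
                        spike_band = c(15, 50), sw_band = c(5, 15),
                        include_broadband = TRUE, dedup_ms = 30,
                        notch_hz = NULL) {
  ev_s <- detect_events(bandpass(rec, spike_band[1], spike_band[2],
                                 notch_hz = notch_hz),
                        k_sd = k_sd, refractory_ms = refractory_ms,
                        min_channels = min_channels, duration_rec = rec)
  ev_w <- detect_events(bandpass(rec, sw_band[1], sw_band[2],
                                 notch_hz = notch_hz),
                        k_sd = k_sd, refractory_ms = refractory_ms,
                        min_channels = min_channels, duration_rec = rec)
  tol <- dedup_ms / 1000 * rec$sampling_rate
  drop_dups <- function(new, kept) {
    if (!nrow(new) || !nrow(kept)) return(new)
    dup <- vapply(new$peak_sample, function(p) {
      any(abs(kept$peak_sample - p) <= tol)
    }, logical(1))
    new[!dup, ]
  }
  ev <- dplyr::bind_rows(ev_s, drop_dups(ev_w, ev_s))
  if (include_broadband) {
    ev_b <- detect_events(rec, k_sd = k_sd, refractory_ms = refractory_ms,
                          min_channels = min_channels, duration_rec = rec)
    ev <- dplyr::bind_rows(ev, drop_dups(ev_b, ev))
  }
  dplyr::arrange(ev, .data$peak_sample)
}

#' Split an event list by kind
#'
#' Partitions events into spikes (duration in \[20, 70) ms) and sharp-waves
#' (\[70, 200\] ms); the boundary duration of exactly 70 ms belongs to the
#' sharp-wave band. Event counts are conserved.
#'
#' @param events an event tibble from [detect_events()].
#' @return A list with elements `spikes` and `sharp_waves`.
#' @export
split_by_kind <- function(events) {
  spikes <- dplyr::filter(events, .data$duration_ms < 70)
  sharp <- dplyr::filter(events, .data$duration_ms >= 70)
  spikes$kind <- rep("spike", nrow(spikes))
  sharp$kind <- rep("sharp_wave", nrow(sharp))
  list(spikes = spikes, sharp_waves = sharp)
}

#' Assemble the electrodes x time x samples IED tensor
#'
#' Extracts a fixed window centered on each event peak; events whose window
#' does not fit inside the recording are dropped (with a message). The mean
#' of the first 20% of the window is subtracted per channel as a baseline.
#'
#' @param rec the `irritmap_recording` to epoch (typically the band-filtered
#'   stream the events came from).
#' @param events event tibble.
#' @param window_ms epoch length, ms (centered on the peak).
#' @return An `irritmap_ied_tensor`: a 3-d array (electrodes x time x
#'   samples) with attributes `sampling_rate`, `window_ms` and `events` (the
#'   retained rows).
#' @export
extract_epochs <- function(rec, events, window_ms = 300) {
  stopifnot(inherits(rec, "irritmap_recording"))
  fs <- rec$sampling_rate
  half <- round(window_ms / 2000 * fs)
  wlen <- 2L * half + 1L
  nt <- ncol(rec$data)
  if (wlen > nt) {
    stop_irritmap("Epoch window is longer than the recording.",
                  "irritmap_epoch_error")
  }
  ok <- events$peak_sample - half >= 1L & events$peak_sample + half <= nt
  if (any(!ok)) {
    message(sprintf("Dropping %d event(s) too close to the recording edge.",
                    sum(!ok)))
  }
  events <- events[ok, ]
  n <- nrow(events)
  arr <- array(0, dim = c(nrow(rec$data), wlen, n))
  nb <- max(1L, floor(0.2 * wlen))
  for (i in seq_len(n)) {
    seg <- rec$data[, (events$peak_sample[i] - half):(events$peak_sample[i] +
                                                        half), drop = FALSE]
    arr[, , i] <- seg - rowMeans(seg[, seq_len(nb), drop = FALSE])
  }
  structure(arr, sampling_rate = fs, window_ms = window_ms,
            channels = rec$channels, events = events,
            class = c("irritmap_ied_tensor", "array"))
}

#' @export
print.irritmap_ied_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<irritmap_ied_tensor> %d electrodes x %d time points x %d samples\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Read / write event tables
#'
#' CSV with columns `peak_s`, `channel`, `amp_uV`, `duration_ms`, `kind`.
#'
#' @param events event tibble.
#' @param path file path.
#' @param sampling_rate used to reconstruct `peak_sample` on read.
#' @return `read_events()` returns the event tibble.
#' @export
write_events <- function(events, path) {
  readr::write_csv(dplyr::select(events, "peak_s", "channel", "amp_uV",
                                 "duration_ms", "kind"), path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, sampling_rate) {
  ev <- readr::read_csv(path, show_col_types = FALSE)
  ev$peak_sample <- as.integer(round(ev$peak_s * sampling_rate)) + 1L
  dplyr::select(ev, "peak_sample", "peak_s", "channel", "amp_uV",
                "duration_ms", "kind")
}
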