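# Zero-phase band-pass (4th-order Butterworth, forward-backward) -- keeps
# event timing intact.
.bandpass <- function(x, fs, band) {
  bf <- signal::butter(4, pmin(band / (fs / 2), 0.99), type = "pass")
  signal::filtfilt(bf, x)
}

# Moving RMS envelope with a boxcar kernel of kernel_s seconds.
.moving_rms <- function(x, fs, kernel_s = 0.2) {
  k <- max(1L, round(kernel_s * fs))
  sq <- stats::filter(x^2, rep(1 / k, k), sides = 2)
  sq[is.na(sq)] <- 0
  sqrt(pmax(as.numeric(sq), 0))
}

.empty_events <- function() {
  data.frame(onset_s = numeric(0), duration_s = numeric(0),
             type = character(0), channel = character(0),
             amplitude = numeric(0))
}

#' Detect sleep spindles in EEG
#'
#' Amplitude-threshold detector in the sigma band: the signal is band-pass
#' filtered to 11-16 Hz (zero-phase), its moving-RMS envelope (0.2-s
#' kernel) is compared against an upper threshold of `thresh_hi` times the
#' channel median envelope; event boundaries extend to where the envelope
#' falls below `thresh_lo` times the median. Durations are restricted to
#' [0.5, 3] s and events separated by less than 0.3 s are merged.
#' Thresholds are relative, so detection is invariant to global amplitude
#' rescaling.
#'
#' @param eeg numeric vector, one channel.
#' @param fs sampling rate (Hz), >= 100.
#' @param band sigma band (Hz).
#' @param thresh_hi,thresh_lo envelope thresholds (multiples of the channel
#'   median envelope).
#' @param dur_range_s admissible event durations (seconds).
#' @param merge_gap_s events closer than this are merged.
#' @param channel channel label recorded in the output.
#' @return event data.frame (onset_s, duration_s, type, channel, amplitude).
#' @export
detect_spindles <- function(eeg, fs, band = c(11, 16),
                            thresh_hi = 3, thresh_lo = 1.25,
                            dur_range_s = c(0.5, 3), merge_gap_s = 0.3,
                            channel = "EEG1") {
  if (fs < 100) stop("EEG sampling rate must be >= 100 Hz")
  if (length(eeg) / fs < 60)
    stop("recording shorter than 60 s: envelope thresholds unstable")
  xf <- .bandpass(eeg, fs, band)
  env <- .moving_rms(xf, fs)
  med <- stats::median(env)
  ev <- .threshold_events(env, fs, thresh_hi * med, thresh_lo * med)
  ev <- ev[ev$duration_s >= dur_range_s[1] & ev$duration_s <= dur_range_s[2], ,
           drop = FALSE]
  ev <- .merge_events(ev, merge_gap_s)
  if (!nrow(ev)) return(.empty_events())
  amp <- vapply(seq_len(nrow(ev)), function(i) {
    i0 <- max(1L, floor(ev$onset_s[i] * fs) + 1L)
    i1 <- min(length(env), ceiling((ev$onset_s[i] + ev$duration_s[i]) * fs))
    max(env[i0:i1])
  }, numeric(1))
  data.frame(onset_s = ev$onset_s, duration_s = ev$duration_s,
             type = "spindle", channel = channel, amplitude = amp)
}

# Hysteresis thresholding of an envelope: events start where env > hi and
# extend outward to the lo crossings.
.threshold_events <- function(env, fs, hi, lo) {
  above_hi <- env > hi
  if (!any(above_hi))
    return(data.frame(onset_s = numeric(0), duration_s = numeric(0)))
  above_lo <- env > lo
  r <- rle(above_lo)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & vapply(seq_along(r$values), function(i) {
    r$values[i] && any(above_hi[starts[i]:ends[i]])
  }, logical(1))
  data.frame(onset_s = (starts[keep] - 1) / fs,
             duration_s = r$lengths[keep] / fs)
}

.merge_events <- function(ev, gap_s) {
  if (nrow(ev) < 2) return(ev)
  ev <- ev[order(ev$onset_s), , drop = FALSE]
  out <- ev[1, , drop = FALSE]
  for (i in 2:nrow(ev)) {
    last_end <- out$onset_s[nrow(out)] + out$duration_s[nrow(out)]
    if (ev$onset_s[i] - last_end < gap_s) {
      out$duration_s[nrow(out)] <-
        ev$onset_s[i] + ev$duration_s[i] - out$onset_s[nrow(out)]
    } else out <- rbind(out, ev[i, ])
  }
  out
}

#' Detect slow waves in EEG
#'
#' Zero-crossing detector in the delta band: the signal is band-pass
#' filtered to 0.5-4 Hz (zero-phase) and segmented at down-going zero
#' crossings. A candidate wave is a negative half-wave of duration 0.25-1 s
#' whose trough falls below `-thresh_mad` times the median absolute
#' deviation of the filtered trace (or below `-abs_uv` microvolts when
#' calibrated units are supplied). The reported event spans the full cycle
#' from the down-going zero crossing to the next down-going crossing.
#'
#' @param eeg numeric vector, one channel.
#' @param fs sampling rate (Hz), >= 100.
#' @param band delta band (Hz).
#' @param thresh_mad trough threshold in MADs of the filtered trace.
#' @param abs_uv optional absolute trough threshold (positive number,
#'   microvolts) used instead of the MAD rule.
#' @param neg_dur_range_s admissible negative half-wave durations.
#' @param channel channel label recorded in the output.
#' @return event data.frame (onset_s, duration_s, type, channel, amplitude);
#'   amplitude is the (negative) trough value.
#' @export
detect_slow_waves <- function(eeg, fs, band = c(0.5, 4),
                              thresh_mad = 3.75, abs_uv = NULL,
                              neg_dur_range_s = c(0.25, 1.0),
                              channel = "EEG1") {
  if (fs < 100) stop("EEG sampling rate must be >= 100 Hz")
  if (length(eeg) / fs < 60)
    stop("recording shorter than 60 s: threshold unstable")
  xf <- .bandpass(eeg, fs, band)
  thr <- if (is.null(abs_uv)) -thresh_mad * stats::mad(xf) else -abs(abs_uv)
  if (thr >= 0 || !any(xf < 0)) return(.empty_events())
  sgn <- sign(xf)
  down <- which(diff(sgn < 0) == 1)   # indices before down-going crossing
  up <- which(diff(sgn > 0) == 1)
  if (length(down) < 2) return(.empty_events())
  ev <- list()
  for (j in seq_len(length(down) - 1L)) {
    a <- down[j]; b <- down[j + 1L]
    u <- up[up > a & up < b]
    neg_end <- if (length(u)) u[1] else b
    neg_dur <- (neg_end - a) / fs
    if (neg_dur < neg_dur_range_s[1] || neg_dur > neg_dur_range_s[2]) next
    trough <- min(xf[a:neg_end])
    if (trough > thr) next
    ev[[length(ev) + 1L]] <- data.frame(
      onset_s = (a - 1) / fs, duration_s = (b - a) / fs,
      type = "slow_wave", channel = channel, amplitude = trough)
  }
  if (!length(ev)) return(.empty_events())
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

#' Bin event occurrence into fixed-width bins
#'
#' Each bin receives the summed overlap, in seconds, between the events'
#' intervals and the bin (intervals half-open [onset, onset + duration)).
#' The total over bins equals the total event duration exactly.
#'
#' @param events event data.frame with onset_s and duration_s.
#' @param bin_s bin width in seconds (default the fMRI TR, 2.08 s).
#' @param span two-element recording span (seconds); bins tile
#'   [span[1], span[2]).
#' @return object of class `activity_trace`: `values` (seconds of event
#'   time per bin), `bin_s`, `bin_starts_s`.
#' @export
bin_activity <- function(events, bin_s = 2.08, span) {
  n_bins <- ceiling((span[2] - span[1]) / bin_s)
  starts <- span[1] + (seq_len(n_bins) - 1) * bin_s
  vals <- numeric(n_bins)
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      a <- events$onset_s[i]; b <- a + events$duration_s[i]
      j <- seq(max(1L, floor((a - span[1]) / bin_s) + 1L),
               min(n_bins, floor((b - span[1]) / bin_s - 1e-12) + 1L))
      vals[j] <- vals[j] + pmin(b, starts[j] + bin_s) - pmax(a, starts[j])
    }
  }
  structure(list(values = vals, bin_s = bin_s, bin_starts_s = starts),
            class = "activity_trace")
}

#' Aggregate a binned activity trace in sliding Hamming windows
#'
#' Weighted average with Hamming weights over sliding windows of
#' `window_bins` bins advanced by `step_bins`, matching the BOLD
#' spectrogram's windowing so the two time courses share window centers.
#'
#' @param binned an `activity_trace` from [bin_activity()].
#' @param window_bins,step_bins window length and step, in bins.
#' @return list with `values` (one per window) and `window_centers_s`.
#' @export
hamming_aggregate <- function(binned, window_bins = 50L, step_bins = 1L) {
  x <- binned$values
  starts <- .window_starts(length(x), window_bins, step_bins)
  w <- .hamming(window_bins)
  vals <- vapply(starts, function(s)
    sum(w * x[(s + 1):(s + window_bins)]) / sum(w), numeric(1))
  # centers coincide with the BOLD spectrogram's when bins align to volumes
  centers <- binned$bin_starts_s[1] +
    (starts + (window_bins - 1) / 2) * binned$bin_s
  list(values = vals, window_centers_s = centers)
}

#' EEG band-power time course with the BOLD windowing contract
#'
#' Sliding-window FFT of the EEG in 104-s Hamming windows advanced by
#' 2.08 s (both expressed in samples at the EEG rate), returning the mean
#' spectral power within the requested band per window. Same demeaning,
#' taper, and normalisation as the BOLD spectrogram.
#'
#' @param eeg numeric vector, one channel.
#' @param fs sampling rate (Hz).
#' @param band two-element band (Hz), e.g. sigma c(11, 16) or delta
#'   c(0.5, 4).
#' @param window_s,step_s window length and step in seconds.
#' @return list with `values`, `window_centers_s`, `band_hz`.
#' @export
eeg_band_power_trace <- function(eeg, fs, band,
                                 window_s = 104, step_s = 2.08) {
  stopifnot(band[1] > 0, band[2] <= fs / 2)
  N <- round(window_s * fs)
  step <- round(step_s * fs)
  starts <- .window_starts(length(eeg), N, step)
  w <- .hamming(N)
  sw2 <- sum(w)^2
  freqs <- (1:(N %/% 2)) * fs / N
  bi <- which(freqs >= band[1] & freqs <= band[2])
  vals <- vapply(starts, function(s) {
    p <- .window_power(eeg[(s + 1):(s + N)], w, sw2)
    mean(p[bi])
  }, numeric(1))
  list(values = vals,
       window_centers_s = (starts + (N - 1) / 2) / fs,
       band_hz = band)
}
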