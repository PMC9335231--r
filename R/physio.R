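# Local-maximum peak picking with a refractory period: keeps the largest
# peak within each refractory window.
.find_peaks <- function(x, fs, refractory_s, min_height = NULL) {
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (is.null(min_height)) min_height <- stats::quantile(x, 0.6)
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  ref <- round(refractory_s * fs)
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= ref) {
      keep <- c(keep, i)
      last <- i
    } else if (x[i] > x[keep[length(keep)]]) {
      keep[length(keep)] <- i
      last <- i
    }
  }
  keep
}

# Linear 0 -> 2 pi phase between successive event indices; NA outside.
.event_phase <- function(n, peaks) {
  ph <- rep(NA_real_, n)
  for (j in seq_len(length(peaks) - 1L)) {
    a <- peaks[j]; b <- peaks[j + 1L]
    ph[a:(b - 1L)] <- 2 * pi * (0:(b - a - 1L)) / (b - a)
  }
  ph
}

#' Build respiratory and cardiac nuisance regressors
#'
#' Derives a RETROICOR-style design from raw physiological traces: cardiac
#' and respiratory phase (sin/cos, Fourier orders 1-2; cardiac phase runs
#' linearly 0 to 2 pi between successive pulse peaks, respiratory phase
#' follows the amplitude-histogram method signed by the derivative),
#' beat-wise cardiac and respiratory rate (per minute, linearly
#' interpolated to volume times), respiratory volume (6-s windowed SD of
#' the trace), and respiratory depth (cycle peak-to-trough). All columns
#' are sampled at volume midpoints.
#'
#' @param resp,cardiac raw traces at `fs_physio` Hz.
#' @param fs_physio physiological sampling rate (Hz).
#' @param tr_s BOLD repetition time (seconds).
#' @param n_volumes number of BOLD volumes.
#' @param card_refractory_s,resp_refractory_s peak-picking refractory
#'   periods.
#' @return object of class `physio_regressors`: numeric matrix (one row
#'   per volume) with named columns, plus `volume_times_s`.
#' @export
build_regressors <- function(resp, cardiac, fs_physio, tr_s, n_volumes,
                             card_refractory_s = 0.35,
                             resp_refractory_s = 1.5) {
  n_volumes <- as.integer(n_volumes)
  t_vol <- (seq_len(n_volumes) - 0.5) * tr_s
  if (max(t_vol) > length(resp) / fs_physio + tr_s)
    stop("physio traces do not cover the BOLD acquisition span")
  tt <- (seq_along(resp) - 1) / fs_physio

  cpk <- .find_peaks(cardiac, fs_physio, card_refractory_s)
  rpk <- .find_peaks(resp, fs_physio, resp_refractory_s)
  if (length(cpk) < 2) stop("fewer than 2 cardiac peaks detected")
  if (length(rpk) < 2) stop("fewer than 2 respiratory cycles detected")

  card_phase <- .event_phase(length(cardiac), cpk)

  # respiratory phase, amplitude-histogram method: position of the current
  # amplitude in the empirical distribution, signed by the slope
  rc <- rank(resp, ties.method = "average") / length(resp)
  drv <- c(diff(resp), 0)
  resp_phase <- pi * rc * sign(drv)          # in (-pi, pi]

  interp <- function(x_t, x, t_out) {
    ok <- !is.na(x)
    stats::approx(x_t[ok], x[ok], xout = t_out, rule = 2)$y
  }
  # beat-wise rates (per minute) placed at interval midpoints
  rate_series <- function(pk) {
    ibi <- diff(pk) / fs_physio
    mid <- tt[pk[-length(pk)]] + ibi / 2
    list(t = mid, v = 60 / ibi)
  }
  cr <- rate_series(cpk)
  rr <- rate_series(rpk)

  # respiratory volume: windowed SD (6-s boxcar)
  k <- max(1L, round(6 * fs_physio))
  m1 <- stats::filter(resp, rep(1 / k, k), sides = 2)
  m2 <- stats::filter(resp^2, rep(1 / k, k), sides = 2)
  rvol <- sqrt(pmax(as.numeric(m2 - m1^2), 0))

  # respiratory depth: per-cycle peak-to-trough at cycle midpoints
  dep_t <- dep_v <- numeric(length(rpk) - 1L)
  for (j in seq_len(length(rpk) - 1L)) {
    seg <- resp[rpk[j]:rpk[j + 1L]]
    dep_v[j] <- max(seg) - min(seg)
    dep_t[j] <- (tt[rpk[j]] + tt[rpk[j + 1L]]) / 2
  }

  cp <- interp(tt, card_phase, t_vol)
  rp <- interp(tt, resp_phase, t_vol)
  m <- cbind(
    resp_phase_sin1 = sin(rp),     resp_phase_cos1 = cos(rp),
    resp_phase_sin2 = sin(2 * rp), resp_phase_cos2 = cos(2 * rp),
    resp_rate       = interp(rr$t, rr$v, t_vol),
    resp_volume     = interp(tt, rvol, t_vol),
    resp_depth      = interp(dep_t, dep_v, t_vol),
    card_phase_sin1 = sin(cp),     card_phase_cos1 = cos(cp),
    card_phase_sin2 = sin(2 * cp), card_phase_cos2 = cos(2 * cp),
    card_rate       = interp(cr$t, cr$v, t_vol))
  if (any(!is.finite(m))) stop("non-finite regressor values after interpolation")
  structure(list(matrix = m, volume_times_s = t_vol), class = "physio_regressors")
}

#' Regress nuisance signals out of BOLD time series
#'
#' Per region, returns the residual of the least-squares projection onto
#' an intercept, a linear drift term, and the supplied regressors.
#' Collinear design columns are dropped (with a message naming them).
#' Residuals are orthogonal to the retained design, and the operation is
#' idempotent.
#'
#' @param ts a [region_ts()].
#' @param regressors a `physio_regressors` or plain numeric matrix with
#'   one row per volume.
#' @return a [region_ts()] of residuals.
#' @export
regress_out <- function(ts, regressors) {
  R <- if (inherits(regressors, "physio_regressors")) regressors$matrix else
    as.matrix(regressors)
  n <- nrow(ts$values)
  if (nrow(R) != n) stop("regressor rows must match BOLD volumes")
  X <- cbind(intercept = 1, drift = seq_len(n) - (n + 1) / 2, R)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    message("dropping collinear regressor(s): ", paste(drop, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  res <- ts$values - X %*% qr.coef(qrX, ts$values)
  region_ts(res, tr_s = ts$tr_s, region_labels = ts$region_labels,
            t0_s = ts$t0_s)
}

#' Alias frequency of a signal sampled at the fMRI rate
#'
#' Folds a true frequency into the sampled band [0, fs/2] with
#' fs = 1/tr_s: r = f mod fs; alias = r if r <= fs/2, else fs - r.
#' A cardiac pulse at 1 Hz sampled at TR = 2.08 s, for instance, aliases
#' to ~0.038 Hz, inside the infra-slow BOLD band.
#'
#' @param f_hz true frequency (Hz), vectorised.
#' @param tr_s sampling interval (seconds).
#' @return aliased frequency (Hz) in [0, 1/(2 tr_s)].
#' @export
alias_frequency <- function(f_hz, tr_s) {
  stopifnot(all(f_hz >= 0), tr_s > 0)
  fs <- 1 / tr_s
  r <- f_hz %% fs
  ifelse(r <= fs / 2, r, fs - r)
}

#' Sliding-window band power of a physiological series
#'
#' Applies the package's sliding-window contract (104-s Hamming windows,
#' 2.08-s steps by default, expressed in samples at the series' own rate)
#' and returns the summed spectral power within the band per window.
#'
#' @param x numeric series.
#' @param fs its sampling rate (Hz).
#' @param band two-element band (Hz) within (0, fs/2].
#' @param window_s,step_s window length and step (seconds).
#' @return list with `values`, `window_centers_s`, `band_hz`.
#' @export
physio_band_power <- function(x, fs, band, window_s = 104, step_s = 2.08) {
  stopifnot(band[2] > band[1], band[1] >= 0, band[2] <= fs / 2)
  N <- round(window_s * fs)
  step <- max(1L, round(step_s * fs))
  starts <- .window_starts(length(x), N, step)
  w <- .hamming(N)
  sw2 <- sum(w)^2
  freqs <- (1:(N %/% 2)) * fs / N
  bi <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(bi)) stop("band narrower than one frequency bin")
  vals <- vapply(starts, function(s)
    sum(.window_power(x[(s + 1):(s + N)], w, sw2)[bi]), numeric(1))
  list(values = vals, window_centers_s = (starts + (N - 1) / 2) / fs,
       band_hz = band)
}

#' Time-averaged power spectrum of a physiological trace
#'
#' Mean over sliding-window spectra (same contract as the BOLD
#' spectrogram); convenience for locating the principal respiratory or
#' cardiac spectral peak.
#'
#' @inheritParams physio_band_power
#' @return list with `freqs_hz`, `power`, and `peak_freq_hz` (frequency of
#'   the largest non-DC spectral value).
#' @export
physio_spectrum <- function(x, fs, window_s = 104, step_s = 2.08) {
  N <- round(window_s * fs)
  step <- max(1L, round(step_s * fs))
  starts <- .window_starts(length(x), N, step)
  w <- .hamming(N)
  sw2 <- sum(w)^2
  freqs <- (1:(N %/% 2)) * fs / N
  acc <- numeric(length(freqs))
  for (s in starts) acc <- acc + .window_power(x[(s + 1):(s + N)], w, sw2)
  pw <- acc / length(starts)
  list(freqs_hz = freqs, power = pw, peak_freq_hz = freqs[which.max(pw)])
}
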