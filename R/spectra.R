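# Hamming taper as used throughout: w[n] = 0.54 - 0.46 cos(2 pi n / (N-1)).
.hamming <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# One-sided power spectrum of a single demeaned, Hamming-tapered window.
# Amplitude-calibrated: a unit-amplitude sinusoid at a bin frequency yields
# power 0.5 at that bin, independent of the taper (normalisation by the
# squared taper sum). DC excluded; the Nyquist bin (even N) is not doubled.
.window_power <- function(x, w, sw2) {
  n <- length(x)
  X <- stats::fft((x - mean(x)) * w)
  nb <- n %/% 2
  p <- 2 * Mod(X[2:(nb + 1)])^2 / sw2
  if (n %% 2 == 0) p[nb] <- p[nb] / 2   # Nyquist bin appears once
  p
}

.window_starts <- function(n, win, step) {
  if (n < win) stop("series shorter than one analysis window")
  seq(0L, n - win, by = step)
}

#' Sliding-window Hamming-tapered FFT spectrogram of regional BOLD
#'
#' Applies FFT analysis in sliding Hamming windows (default 50 volumes,
#' i.e. 104 s at TR = 2.08 s) advanced by 1 volume. Each window is demeaned,
#' tapered, and its one-sided magnitude-squared spectrum normalised by the
#' squared taper sum, so a unit-amplitude sinusoid at a bin frequency
#' yields band power 0.5 regardless of taper. The DC bin is excluded.
#'
#' @param ts a [region_ts()].
#' @param window_volumes window length in volumes.
#' @param step_volumes step between window starts in volumes.
#' @return object of class `bold_spectrogram`: `power` array
#'   (frequency x window x region), `freqs_hz`, `window_centers_s`, and the
#'   windowing metadata.
#' @export
sliding_spectrogram <- function(ts, window_volumes = 50L, step_volumes = 1L) {
  stopifnot(inherits(ts, "region_ts"))
  n <- nrow(ts$values)
  N <- as.integer(window_volumes)
  starts <- .window_starts(n, N, step_volumes)
  fs <- 1 / ts$tr_s
  w <- .hamming(N)
  sw2 <- sum(w)^2
  nb <- N %/% 2
  freqs <- (1:nb) * fs / N

  pow <- array(0, c(nb, length(starts), ncol(ts$values)),
               dimnames = list(NULL, NULL, ts$region_labels))
  for (r in seq_len(ncol(ts$values))) {
    xr <- ts$values[, r]
    for (i in seq_along(starts)) {
      seg <- xr[(starts[i] + 1):(starts[i] + N)]
      pow[, i, r] <- .window_power(seg, w, sw2)
    }
  }
  structure(list(
    power = pow, freqs_hz = freqs,
    window_centers_s = ts$t0_s + (starts + (N - 1) / 2) * ts$tr_s,
    window_len_volumes = N, step_volumes = as.integer(step_volumes),
    taper = "hamming", tr_s = ts$tr_s, region_labels = ts$region_labels),
    class = "bold_spectrogram")
}

#' @export
print.bold_spectrogram <- function(x, ...) {
  cat("<bold_spectrogram>", dim(x$power)[1], "freqs x", dim(x$power)[2],
      "windows x", dim(x$power)[3], "regions;",
      sprintf("%.2f", x$window_len_volumes * x$tr_s), "s Hamming windows\n")
  invisible(x)
}

#' Assign a sleep stage to each analysis window
#'
#' A window takes the stage of the majority of its volumes; windows in
#' which no single stage covers at least `purity` of the volumes are
#' labelled "transition" (excluded from stage averages, retained for lag
#' analysis).
#'
#' @param spec a `bold_spectrogram` (or any object with the same windowing
#'   fields).
#' @param hyp a `hypnogram`.
#' @param purity minimum single-stage fraction for a clean label.
#' @return character vector, one label per window.
#' @export
window_stages <- function(spec, hyp, purity = 0.8) {
  N <- spec$window_len_volumes
  tr <- spec$tr_s
  vapply(spec$window_centers_s, function(ct) {
    tv <- ct + (seq_len(N) - (N + 1) / 2) * tr
    st <- stage_at(hyp, pmax(tv, 0))
    tab <- table(st)
    top <- which.max(tab)
    if (tab[top] / N >= purity) names(tab)[top] else "transition"
  }, character(1))
}

#' Stage-averaged BOLD power spectrum
#'
#' Mean spectrum over all clean windows of one sleep stage, per region.
#'
#' @param spec a `bold_spectrogram`.
#' @param hyp a `hypnogram`.
#' @param stage one of W, N1, N2, N3, R.
#' @param min_windows minimum clean windows required for the stage.
#' @return list with `available`; when available, `spectrum` (frequency x
#'   region matrix), `freqs_hz`, `n_windows`; otherwise `reason`.
#' @export
stage_average_spectrum <- function(spec, hyp, stage, min_windows = 30L) {
  ws <- window_stages(spec, hyp)
  sel <- which(ws == stage)
  if (length(sel) < min_windows) {
    return(list(available = FALSE, stage = stage, n_windows = length(sel),
                reason = sprintf(
                  "only %d clean '%s' windows (need >= %d)",
                  length(sel), stage, min_windows)))
  }
  sp <- apply(spec$power[, sel, , drop = FALSE], c(1, 3), mean)
  list(available = TRUE, stage = stage, spectrum = sp,
       freqs_hz = spec$freqs_hz, n_windows = length(sel))
}

#' Fit the scale-free 1/f trend of a power spectrum
#'
#' Robust (iteratively reweighted, Huber) least-squares line in
#' log10(power) against log10(frequency) over the fit range, excluding the
#' oscillation search ranges so residual peaks do not bias the aperiodic
#' estimate. Non-positive power bins are dropped from the fit and counted.
#'
#' @param freqs_hz frequency grid (Hz).
#' @param power spectrum values (same length).
#' @param fit_range_hz two-element range used for the fit.
#' @param exclude_ranges_hz list of ranges excluded from the fit (the peak
#'   search ranges by default).
#' @return list with `slope`, `intercept` (log10 units), `residual`
#'   (log10 power minus fitted line, full grid), `fit_idx`, and
#'   `n_nonpositive`.
#' @export
fit_one_over_f <- function(freqs_hz, power,
                           fit_range_hz = c(0.01, 0.22),
                           exclude_ranges_hz = list(c(0.03, 0.08),
                                                    c(0.13, 0.19))) {
  keep <- freqs_hz >= fit_range_hz[1] & freqs_hz <= fit_range_hz[2]
  for (ex in exclude_ranges_hz)
    keep <- keep & !(freqs_hz >= ex[1] & freqs_hz <= ex[2])
  npos <- sum(keep & power <= 0)
  keep <- keep & power > 0
  if (sum(keep) < 10)
    stop("fewer than 10 positive bins in the 1/f fit range after exclusions")
  lx <- log10(freqs_hz[keep])
  ly <- log10(power[keep])
  fit <- .huber_line(lx, ly)
  fitted_full <- fit$intercept + fit$slope * log10(freqs_hz)
  lp <- ifelse(power > 0, log10(power), NA_real_)
  list(slope = fit$slope, intercept = fit$intercept,
       residual = lp - fitted_full, fit_idx = which(keep),
       n_nonpositive = npos)
}

# Huber-weighted iteratively reweighted least-squares line fit.
.huber_line <- function(x, y, k = 1.345, max_iter = 30L, tol = 1e-8) {
  w <- rep(1, length(x))
  b <- c(0, 0)
  for (i in seq_len(max_iter)) {
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    if (max(abs(fit$coefficients - b)) < tol) break
    b <- fit$coefficients
    r <- as.numeric(y - cbind(1, x) %*% b)
    s <- stats::mad(r)
    if (s <= 0) break
    u <- abs(r / s)
    w <- ifelse(u <= k, 1, k / u)
  }
  list(intercept = unname(b[1]), slope = unname(b[2]))
}

#' Detect low- and high-frequency oscillation peaks above the 1/f trend
#'
#' Within each search range, the peak is the frequency of maximum 1/f-fit
#' residual, accepted only if it exceeds `threshold_sd` robust standard
#' deviations (MAD) of the residuals over the fit bins. The oscillation
#' band is the peak plus/minus a half-width, truncated to the search range.
#' A no-peak outcome is explicit (`detected = FALSE`).
#'
#' @param freqs_hz frequency grid.
#' @param fit result of [fit_one_over_f()].
#' @param lf_search,hf_search search ranges (Hz); LF must lie below 0.1 Hz,
#'   HF above.
#' @param threshold_sd detection threshold in robust SDs of the residual.
#' @param half_width_hz named c(LF=, HF=) band half-widths (Hz).
#' @return list of two `oscillation_band` lists (`kind`, `detected`,
#'   `peak_freq_hz`, `band_hz`, `search_range_hz`, `residual_peak`).
#' @export
detect_band_peaks <- function(freqs_hz, fit,
                              lf_search = c(0.03, 0.08),
                              hf_search = c(0.13, 0.19),
                              threshold_sd = 2,
                              half_width_hz = c(LF = 0.015, HF = 0.03)) {
  stopifnot(lf_search[2] < 0.1, hf_search[1] > 0.1)
  res <- fit$residual
  thr <- threshold_sd * stats::mad(res[fit$fit_idx], na.rm = TRUE)
  one <- function(kind, range) {
    idx <- which(freqs_hz >= range[1] & freqs_hz <= range[2] & !is.na(res))
    if (!length(idx))
      return(list(kind = kind, detected = FALSE, peak_freq_hz = NA_real_,
                  band_hz = c(NA_real_, NA_real_), search_range_hz = range,
                  residual_peak = NA_real_))
    pk <- idx[which.max(res[idx])]
    det <- res[pk] > thr
    hw <- half_width_hz[[kind]]
    band <- c(max(freqs_hz[pk] - hw, range[1]),
              min(freqs_hz[pk] + hw, range[2]))
    list(kind = kind, detected = det,
         peak_freq_hz = if (det) freqs_hz[pk] else NA_real_,
         band_hz = if (det) band else c(NA_real_, NA_real_),
         search_range_hz = range, residual_peak = res[pk])
  }
  list(LF = one("LF", lf_search), HF = one("HF", hf_search))
}

#' Band power time course from a spectrogram
#'
#' Per window, the mean power over the band's frequency bins. A band
#' narrower than one bin falls back to the nearest single bin with a
#' warning.
#'
#' @param spec a `bold_spectrogram`.
#' @param band two-element numeric band (Hz) or an `oscillation_band` from
#'   [detect_band_peaks()].
#' @param region region label or index; NULL returns all regions.
#' @return object of class `power_trace`: `values` (window x region
#'   matrix), `band_hz`, `window_centers_s`, windowing metadata.
#' @export
band_power_trace <- function(spec, band, region = NULL) {
  if (is.list(band)) band <- band$band_hz
  if (any(is.na(band))) stop("band is undefined (no peak detected?)")
  idx <- which(spec$freqs_hz >= band[1] & spec$freqs_hz <= band[2])
  if (!length(idx)) {
    idx <- which.min(abs(spec$freqs_hz - mean(band)))
    warning("band narrower than one frequency bin; using nearest bin at ",
            signif(spec$freqs_hz[idx], 3), " Hz")
  }
  pow <- spec$power
  if (!is.null(region)) pow <- pow[, , region, drop = FALSE]
  vals <- apply(pow[idx, , , drop = FALSE], c(2, 3), mean)
  structure(list(values = vals, band_hz = band,
                 window_centers_s = spec$window_centers_s,
                 window_len_volumes = spec$window_len_volumes,
                 step_volumes = spec$step_volumes, tr_s = spec$tr_s,
                 region_labels = dimnames(pow)[[3]]),
            class = "power_trace")
}

#' @export
print.power_trace <- function(x, ...) {
  cat("<power_trace>", nrow(x$values), "windows x", ncol(x$values),
      "regions; band", sprintf("%.3f-%.3f Hz", x$band_hz[1], x$band_hz[2]),
      "\n")
  invisible(x)
}

#' Percent change in oscillation power from a baseline stage
#'
#' 100 x (mean target-stage power - mean baseline power) / mean baseline
#' power, per region, using clean (non-transition) windows only.
#'
#' @param trace a `power_trace`.
#' @param hyp a `hypnogram`.
#' @param baseline_stage baseline stage label (default W).
#' @param target_stages stages pooled as the target (default N1, N2, N3).
#' @param min_windows minimum clean windows in each of the two sets.
#' @return named numeric vector, percent change per region.
#' @export
percent_power_change <- function(trace, hyp, baseline_stage = "W",
                                 target_stages = c("N1", "N2", "N3"),
                                 min_windows = 30L) {
  ws <- window_stages(trace, hyp)
  b <- which(ws == baseline_stage)
  s <- which(ws %in% target_stages)
  if (length(b) < min_windows || length(s) < min_windows)
    stop(sprintf("need >= %d clean windows per stage set (have %d baseline, %d target)",
                 min_windows, length(b), length(s)))
  pb <- colMeans(trace$values[b, , drop = FALSE])
  if (any(pb <= 0)) stop("baseline mean power non-positive")
  ps <- colMeans(trace$values[s, , drop = FALSE])
  stats::setNames(100 * (ps - pb) / pb, trace$region_labels)
}
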