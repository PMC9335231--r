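#' Region-by-time BOLD container
#'
#' @param values numeric matrix, volumes in rows, regions in columns.
#' @param tr_s repetition time (seconds).
#' @param region_labels unique region identifiers (default column names or
#'   R1..Rn).
#' @param t0_s acquisition start time (seconds).
#' @return object of class `region_ts`.
#' @export
region_ts <- function(values, tr_s, region_labels = NULL, t0_s = 0) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("region_ts values must be finite")
  stopifnot(tr_s > 0)
  if (is.null(region_labels))
    region_labels <- colnames(values) %||% paste0("R", seq_len(ncol(values)))
  if (anyDuplicated(region_labels)) stop("region labels must be unique")
  colnames(values) <- region_labels
  structure(list(values = values, tr_s = tr_s,
                 region_labels = region_labels, t0_s = t0_s),
            class = "region_ts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.region_ts <- function(x, ...) {
  cat("<region_ts>", nrow(x$values), "volumes x", ncol(x$values),
      "regions, TR", x$tr_s, "s\n")
  invisible(x)
}

#' Volume acquisition times of a region_ts
#' @param ts a `region_ts`.
#' @return numeric vector of volume times (seconds).
#' @export
volume_times <- function(ts) ts$t0_s + (seq_len(nrow(ts$values)) - 1) * ts$tr_s

#' Colored (1/f^beta) Gaussian noise by frequency-domain shaping
#'
#' White Gaussian noise is shaped in the frequency domain so its power
#' spectrum is proportional to 1/f^beta; the DC bin is zeroed and the
#' result rescaled to the requested RMS. Gives exact spectral control,
#' unlike AR approximations.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param beta spectral exponent (power ~ 1/f^beta); 0 gives white noise.
#' @param sd target RMS of the output.
#' @return numeric vector of length `n`.
#' @export
one_over_f_noise <- function(n, fs, beta = 1, sd = 1) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  # two-sided frequency axis: mirror upper half
  f[f > fs / 2] <- fs - f[f > fs / 2]
  shape <- ifelse(f > 0, f^(-beta / 2), 0)
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x <- x * (sd / s)
  x
}

# Half-cosine smoothing of a stepwise gain series: each stage step becomes
# a raised-cosine ramp of length ramp_s, shorter than one analysis window.
.ramp_gains <- function(g, dt, ramp_s) {
  k <- max(1L, round(ramp_s / dt))
  if (k <= 1L) return(g)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(k) / (k + 1)))
  w <- w / sum(w)
  n <- length(g)
  gp <- c(rep(g[1], k), g, rep(g[n], k))
  out <- stats::filter(gp, w, sides = 2)
  as.numeric(out[(k + 1):(k + n)])
}

# Stage-gain time course for one region/band: stage looked up at t - lag,
# mapped through the gain table, then ramped.
.gain_course <- function(hyp, t_s, lag_s, stage_gain, band_idx, dt, ramp_s) {
  st <- stage_at(hyp, pmax(t_s - lag_s, 0))
  g <- vapply(st, function(s) stage_gain[[s]][band_idx], numeric(1))
  .ramp_gains(g, dt, ramp_s)
}

#' Simulate regional BOLD time series
#'
#' Each region's signal is a 1/f^beta background plus two stage-gated
#' sinusoids: a low-frequency oscillation (region-specific frequency in the
#' infra-slow range) and a higher-frequency oscillation. Gains follow the
#' hypnogram's stage, delayed per region by the configured onset lag on
#' wake-to-sleep steps (and offset lag on sleep-to-wake steps), with smooth
#' 20-s half-cosine transitions.
#'
#' @param config a [sim_config()].
#' @param hyp a `hypnogram` covering the recording.
#' @return a [region_ts()].
#' @export
simulate_bold <- function(config, hyp) {
  stopifnot(inherits(config, "sim_config"), inherits(hyp, "hypnogram"))
  tr <- config$tr_s
  nyq <- 1 / (2 * tr)
  if (any(c(config$lf_freq_hz, config$hf_freq_hz) > nyq))
    stop(sprintf("injected frequency above BOLD Nyquist (%.4f Hz)", nyq))
  n_vol <- floor(config$duration_s / tr)
  t <- (seq_len(n_vol) - 1) * tr
  fs <- 1 / tr

  rs <- .sub_rng(config$seed, 1L)
  on.exit(.restore_rng(rs))
  phi <- stats::runif(config$n_regions, 0, 2 * pi)
  psi <- stats::runif(config$n_regions, 0, 2 * pi)

  # onset vs offset lags: onset lag governs the falling-asleep half of the
  # sleep bout, offset lag the waking half; the switch sits mid-bout where
  # gains are constant so it introduces no discontinuity.
  st <- stage_at(hyp, t)
  sleep <- st %in% c("N1", "N2", "N3", "R")
  t_mid <- if (any(sleep)) mean(range(t[sleep])) else config$duration_s

  vals <- matrix(0, n_vol, config$n_regions)
  for (r in seq_len(config$n_regions)) {
    bg <- one_over_f_noise(n_vol, fs, config$one_over_f_exponent,
                           config$bold_background_sd)
    # independent slow amplitude envelope, drawn per region
    amp_env <- if (config$bold_amp_mod > 0)
      1 + config$bold_amp_mod * .band_limited_noise(n_vol, fs, c(0.005, 0.03))
    else 1
    lag_r <- ifelse(t <= t_mid, config$onset_lag_s[r], config$offset_lag_s[r])
    g_lf <- .gain_course(hyp, t, lag_r, config$stage_gain, 1L, tr, config$ramp_s)
    g_hf <- .gain_course(hyp, t, lag_r, config$stage_gain, 2L, tr, config$ramp_s)
    vals[, r] <- amp_env * (bg +
      g_lf * sin(2 * pi * config$lf_freq_hz[r] * t + phi[r]) +
      g_hf * sin(2 * pi * config$hf_freq_hz[r] * t + psi[r]))
  }
  region_ts(vals, tr_s = tr,
            region_labels = paste0("R", seq_len(config$n_regions)))
}
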