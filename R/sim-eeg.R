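# Band-limited RMS of a series, used to scale injected events relative to
# the background in their own band.
.band_rms <- function(x, fs, band) {
  bf <- signal::butter(4, pmin(band / (fs / 2), 0.99), type = "pass")
  stats::sd(signal::filtfilt(bf, x))
}

# Inhomogeneous Poisson event onsets on [0, T) by thinning: candidates are
# drawn at the peak rate and kept with probability rate(t)/rate_max, where
# rate(t) = base(stage(t)) * (1 + m sin(2 pi f_env t)). The envelope has
# mean 1 so the stage base rate is preserved in expectation.
.thinned_events <- function(hyp, duration_s, rates_per_min, f_env, mod_depth) {
  base <- rates_per_min / 60
  rmax <- max(base) * (1 + mod_depth)
  if (rmax <= 0) return(numeric(0))
  n_cand <- stats::rpois(1, rmax * duration_s)
  tc <- sort(stats::runif(n_cand, 0, duration_s))
  env <- 1 + mod_depth * sin(2 * pi * f_env * tc)
  rate <- base[stage_at(hyp, tc)] * env
  tc[stats::runif(n_cand) < rate / rmax]
}

#' Simulate EEG with spindle and slow-wave events
#'
#' Generates pink-noise background EEG plus sleep spindles (11-16 Hz
#' Hann-tapered bursts, 0.5-2 s) and slow waves (biphasic delta-band waves,
#' negative phase first). Event onsets follow an inhomogeneous Poisson
#' process: the stage-specific base rate times an infra-slow sinusoidal
#' envelope at the mean injected BOLD oscillation frequency (low-frequency
#' envelope for spindles, high-frequency envelope for slow waves),
#' implemented by thinning. Event amplitudes are set as multiples of the
#' background RMS in the event's own band.
#'
#' @param config a [sim_config()].
#' @param hyp a `hypnogram`.
#' @param overlap_limit maximum tolerated expected event-time fraction per
#'   stage (rate x max duration); higher rates are rejected.
#' @return list with `eeg` (numeric vector, one channel), `fs`, and
#'   `events_truth` (data.frame: onset_s, duration_s, type, channel,
#'   amplitude).
#' @export
simulate_eeg <- function(config, hyp, overlap_limit = 0.5) {
  stopifnot(inherits(config, "sim_config"), inherits(hyp, "hypnogram"))
  fs <- config$eeg_fs_hz
  n <- floor(config$duration_s * fs)
  dur_max <- c(spindle = 2, slow_wave = 1.5)
  for (ty in c("spindle", "slow_wave")) {
    rates <- if (ty == "spindle") config$spindle_rate_per_min else config$sw_rate_per_min
    if (max(rates) / 60 * dur_max[[ty]] > overlap_limit)
      stop(ty, " rate too high: expected overlap fraction exceeds ",
           overlap_limit)
  }

  rs <- .sub_rng(config$seed, 2L)
  on.exit(.restore_rng(rs))

  eeg <- one_over_f_noise(n, fs, beta = 1, sd = 1)
  sigma_rms <- .band_rms(eeg, fs, c(11, 16))
  delta_rms <- .band_rms(eeg, fs, c(0.5, 4))

  f_lf <- mean(config$lf_freq_hz)
  f_hf <- mean(config$hf_freq_hz)

  sp_on <- .thinned_events(hyp, config$duration_s, config$spindle_rate_per_min,
                           f_lf, config$env_mod_depth)
  sw_on <- .thinned_events(hyp, config$duration_s, config$sw_rate_per_min,
                           f_hf, config$env_mod_depth)

  # Tukey taper (cosine ramps over a fraction r of the burst): spindles wax
  # quickly, so detected onsets track true onsets closely.
  tukey <- function(m, r = 0.25) {
    t <- (seq_len(m) - 1) / (m - 1)
    w <- rep(1, m)
    lo <- t < r / 2
    hi <- t > 1 - r / 2
    w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / r - 1)))
    w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / r - 1)))
    w
  }
  add_spindle <- function(t0) {
    dur <- stats::runif(1, 0.5, 2)
    f <- stats::runif(1, 11, 16)
    i0 <- floor(t0 * fs) + 1L
    k <- seq_len(round(dur * fs))
    if (i0 + length(k) - 1L > n) return(NULL)
    taper <- tukey(length(k))
    amp <- config$spindle_amp_rms * sigma_rms * sqrt(2)
    eeg[i0 + k - 1L] <<- eeg[i0 + k - 1L] +
      amp * taper * sin(2 * pi * f * (k - 1) / fs)
    c(dur, amp)
  }
  add_sw <- function(t0) {
    period <- stats::runif(1, 0.8, 1.5)   # 0.67-1.25 Hz, inside delta
    i0 <- floor(t0 * fs) + 1L
    k <- seq_len(round(period * fs))
    if (i0 + length(k) - 1L > n) return(NULL)
    amp <- config$sw_amp_rms * delta_rms
    # biphasic: negative half-wave then positive rebound
    eeg[i0 + k - 1L] <<- eeg[i0 + k - 1L] -
      amp * sin(2 * pi * (k - 1) / length(k))
    c(period, amp)
  }

  ev <- list()
  for (t0 in sp_on) {
    m <- add_spindle(t0)
    if (!is.null(m))
      ev[[length(ev) + 1L]] <- data.frame(onset_s = t0, duration_s = m[1],
                                          type = "spindle", channel = "EEG1",
                                          amplitude = m[2])
  }
  for (t0 in sw_on) {
    m <- add_sw(t0)
    if (!is.null(m))
      ev[[length(ev) + 1L]] <- data.frame(onset_s = t0, duration_s = m[1],
                                          type = "slow_wave", channel = "EEG1",
                                          amplitude = m[2])
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(onset_s = numeric(0), duration_s = numeric(0),
               type = character(0), channel = character(0),
               amplitude = numeric(0))
  events <- events[order(events$onset_s), , drop = FALSE]
  rownames(events) <- NULL
  list(eeg = eeg, fs = fs, events_truth = events)
}
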