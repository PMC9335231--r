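# Zero-mean unit-RMS noise band-limited to `band` (Hz) by frequency-domain
# masking; exact band control at any sampling rate.
.band_limited_noise <- function(n, fs, band = c(0.04, 0.4)) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]
  X[f < band[1] | f > band[2]] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Simulate raw respiratory and cardiac traces
#'
#' The respiratory trace is a sinusoid-like waveform whose instantaneous
#' rate and depth fluctuate slowly (band-limited random walks with power in
#' 0.04-0.4 Hz); the cardiac trace is a periodic peaked pulse waveform with
#' slowly varying rate. Setting the variability parameters to zero yields
#' strictly periodic traces. Ground-truth instantaneous rate and depth
#' time courses are returned alongside the raw traces.
#'
#' @param config a [sim_config()].
#' @return list with `resp`, `cardiac` (numeric traces), `fs`, and `truth`
#'   (data.frame of instantaneous resp_rate_hz, resp_depth, cardiac_rate_hz
#'   per sample).
#' @export
simulate_physio <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$physio_fs_hz
  if (config$resp_freq_hz >= fs / 2 || config$cardiac_freq_hz >= fs / 2)
    stop("physiological frequency at or above physio Nyquist")
  n <- floor(config$duration_s * fs)
  dt <- 1 / fs

  rs <- .sub_rng(config$seed, 3L)
  on.exit(.restore_rng(rs))

  mod <- function(rel_sd) {
    if (rel_sd <= 0) rep(0, n) else rel_sd * .band_limited_noise(n, fs)
  }
  resp_rate <- config$resp_freq_hz * (1 + mod(config$resp_rate_var))
  resp_rate <- pmax(resp_rate, 0.05 * config$resp_freq_hz)
  resp_depth <- 1 + mod(config$resp_depth_var)
  resp_depth <- pmax(resp_depth, 0.1)
  card_rate <- config$cardiac_freq_hz * (1 + mod(config$cardiac_rate_var))
  card_rate <- pmax(card_rate, 0.05 * config$cardiac_freq_hz)

  phi_r <- 2 * pi * cumsum(resp_rate) * dt
  phi_c <- 2 * pi * cumsum(card_rate) * dt

  resp <- resp_depth * sin(phi_r)
  # peaked pulse waveform: raised cosine to the 4th power, zero-mean-ish
  pulse <- (0.5 + 0.5 * cos(phi_c))^4
  cardiac <- pulse - mean(pulse)

  list(resp = resp, cardiac = cardiac, fs = fs,
       truth = data.frame(t_s = (seq_len(n) - 1) * dt,
                          resp_rate_hz = resp_rate,
                          resp_depth = resp_depth,
                          cardiac_rate_hz = card_rate))
}

#' Generate a complete synthetic recording
#'
#' Convenience wrapper producing all modalities from one configuration:
#' hypnogram, regional BOLD, one-channel EEG with ground-truth events, and
#' raw physiological traces. Identical configurations (including seed)
#' yield bitwise-identical recordings.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_recording`: list with `bold`
#'   ([region_ts()]), `eeg`, `eeg_fs`, `events_truth`, `physio`,
#'   `hypnogram`, and `truth` (the config echo).
#' @export
simulate_recording <- function(config = sim_config()) {
  hyp <- simulate_hypnogram(config)
  bold <- simulate_bold(config, hyp)
  ee <- simulate_eeg(config, hyp)
  ph <- simulate_physio(config)
  structure(list(bold = bold, eeg = ee$eeg, eeg_fs = ee$fs,
                 events_truth = ee$events_truth, physio = ph,
                 hypnogram = hyp, truth = config),
            class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat("<synthetic_recording>", x$truth$duration_s, "s:",
      ncol(x$bold$values), "BOLD regions, 1 EEG channel,",
      nrow(x$events_truth), "truth events\n")
  invisible(x)
}
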