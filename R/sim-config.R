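#' Simulation configuration for synthetic sleep fMRI-EEG recordings
#'
#' Builds the parameter set driving the synthetic-data generator. Defaults
#' emulate the statistical structure the analysis pipeline assumes: BOLD
#' sampled at TR = 2.08 s with a scale-free 1/f background plus
#' stage-gated sinusoidal oscillations (a low-frequency one at 0.04-0.07 Hz
#' and a higher-frequency one at 0.15-0.18 Hz, region-specific frequencies),
#' EEG at 250 Hz with spindle (11-16 Hz) and slow-wave (0.5-4 Hz) events
#' whose occurrence rates are modulated by infra-slow envelopes, and
#' respiratory (~0.25 Hz) and cardiac (~1 Hz) traces with slow rate and
#' depth variability.
#'
#' Stage gains are amplitude multipliers on the injected sinusoids. The
#' defaults profile the two bands across stages (low-frequency oscillation
#' strongest in N2, attenuated in N3; high-frequency oscillation strongest
#' in N3) while keeping the duration-weighted sleep/wake power step at
#' 3.5x for both bands under the default hypnogram -- the calibration used
#' throughout the package's recovery checks.
#'
#' @param seed integer seed; all generator draws derive from it.
#' @param duration_s recording length in seconds (>= 1040 s).
#' @param tr_s fMRI repetition time in seconds.
#' @param n_regions number of brain regions.
#' @param eeg_fs_hz EEG sampling rate (Hz); must exceed 32 Hz.
#' @param physio_fs_hz physiological trace sampling rate (Hz).
#' @param lf_freq_hz per-region low-frequency oscillation frequency (Hz);
#'   if NULL, drawn uniformly in `lf_range`.
#' @param hf_freq_hz per-region high-frequency oscillation frequency (Hz);
#'   if NULL, drawn uniformly in `hf_range`.
#' @param lf_range,hf_range sampling ranges for the per-region frequencies.
#' @param stage_gain named list mapping stage (W, N1, N2, N3, R) to a
#'   length-2 numeric `c(lf_gain, hf_gain)` of non-negative amplitude gains.
#' @param onset_lag_s,offset_lag_s per-region delays (seconds) applied to
#'   the stage-gain time course at falling-asleep / waking transitions.
#' @param ramp_s half-cosine ramp length (seconds) for stage-gain
#'   transitions.
#' @param spindle_rate_per_min,sw_rate_per_min named numeric vectors of
#'   stage-specific event rates (events/min).
#' @param spindle_amp_rms,sw_amp_rms event amplitude as a multiple of the
#'   EEG background RMS in the event's own band (sigma / delta).
#' @param env_mod_depth modulation depth (0-1) of the infra-slow envelope
#'   that groups EEG events.
#' @param resp_freq_hz,cardiac_freq_hz base respiratory / cardiac pulse
#'   frequencies (Hz).
#' @param resp_rate_var,resp_depth_var,cardiac_rate_var relative standard
#'   deviation of the slow (0.04-0.4 Hz band-limited) fluctuations of
#'   instantaneous rate and depth; 0 gives strictly periodic traces.
#' @param one_over_f_exponent exponent beta of the 1/f^beta BOLD background.
#' @param bold_amp_mod relative SD of a slow (0.005-0.03 Hz) multiplicative
#'   amplitude envelope applied to the whole BOLD signal, independent of
#'   the hypnogram; 0 disables it. Used for amplitude-control null
#'   analyses.
#' @param bold_background_sd RMS of the BOLD background noise.
#' @param hyp_dwell_s dwell times (seconds) of the six hypnogram segments
#'   W, N1, N2, N3, N2, W; if NULL, scaled from the default proportions to
#'   `duration_s`.
#' @param epoch_s hypnogram epoch length (seconds).
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       duration_s = 3600,
                       tr_s = 2.08,
                       n_regions = 12L,
                       eeg_fs_hz = 250,
                       physio_fs_hz = 50,
                       lf_freq_hz = NULL,
                       hf_freq_hz = NULL,
                       lf_range = c(0.04, 0.07),
                       hf_range = c(0.15, 0.18),
                       stage_gain = NULL,
                       onset_lag_s = NULL,
                       offset_lag_s = NULL,
                       ramp_s = 20,
                       spindle_rate_per_min = c(W = 0, N1 = 1, N2 = 2, N3 = 1, R = 0),
                       sw_rate_per_min = c(W = 0, N1 = 1, N2 = 3, N3 = 7, R = 0),
                       spindle_amp_rms = 5,
                       sw_amp_rms = 6,
                       env_mod_depth = 0.8,
                       resp_freq_hz = 0.25,
                       cardiac_freq_hz = 1.0,
                       resp_rate_var = 0.08,
                       resp_depth_var = 0.2,
                       cardiac_rate_var = 0.05,
                       one_over_f_exponent = 1.0,
                       bold_amp_mod = 0,
                       bold_background_sd = 1.0,
                       hyp_dwell_s = NULL,
                       epoch_s = 30) {
  stopifnot(tr_s > 0, duration_s >= 10 * 104,
            eeg_fs_hz >= 2 * 16, n_regions >= 1)
  seed <- as.integer(seed)

  if (is.null(stage_gain)) {
    # Stage-profiled amplitudes: the low-frequency oscillation is most
    # prominent in N2 and attenuated in N3; the high-frequency oscillation
    # grows from N1 to N3. Squared gains (power ratios vs wake) are
    # LF: N1 3.0, N2 4.6, N3 2.2 and HF: N1 2.0, N2 3.0, N3 4.67, chosen so
    # the duration-weighted sleep/wake power ratio under the default
    # hypnogram (N1:N2:N3 = 10:40:30 epochs) is 3.5 for both bands.
    stage_gain <- list(W  = c(1, 1),
                       N1 = c(sqrt(3.0), sqrt(2.0)),
                       N2 = c(sqrt(4.6), sqrt(3.0)),
                       N3 = c(sqrt(2.2), sqrt(14 / 3)),
                       R  = c(1, 1))
  }
  stopifnot(all(c("W", "N1", "N2", "N3", "R") %in% names(stage_gain)),
            all(vapply(stage_gain, function(x) all(x >= 0) && length(x) == 2,
                       logical(1))))

  # per-region frequency draws are part of the config so the injected truth
  # travels with it
  rs <- .sub_rng(seed, 101L)
  if (is.null(lf_freq_hz))
    lf_freq_hz <- stats::runif(n_regions, lf_range[1], lf_range[2])
  if (is.null(hf_freq_hz))
    hf_freq_hz <- stats::runif(n_regions, hf_range[1], hf_range[2])
  .restore_rng(rs)
  lf_freq_hz <- rep_len(lf_freq_hz, n_regions)
  hf_freq_hz <- rep_len(hf_freq_hz, n_regions)
  nyq <- 1 / (2 * tr_s)
  if (any(lf_freq_hz >= hf_freq_hz))
    stop("each region's lf_freq_hz must be below its hf_freq_hz")
  if (any(hf_freq_hz > nyq))
    stop(sprintf("oscillation frequency above BOLD Nyquist (%.4f Hz)", nyq))

  if (is.null(onset_lag_s))  onset_lag_s  <- rep(0, n_regions)
  if (is.null(offset_lag_s)) offset_lag_s <- rep(0, n_regions)
  onset_lag_s  <- rep_len(onset_lag_s, n_regions)
  offset_lag_s <- rep_len(offset_lag_s, n_regions)

  cfg <- list(
    seed = seed, duration_s = duration_s, tr_s = tr_s,
    n_regions = as.integer(n_regions),
    eeg_fs_hz = eeg_fs_hz, physio_fs_hz = physio_fs_hz,
    lf_freq_hz = lf_freq_hz, hf_freq_hz = hf_freq_hz,
    stage_gain = stage_gain,
    onset_lag_s = onset_lag_s, offset_lag_s = offset_lag_s,
    ramp_s = ramp_s,
    spindle_rate_per_min = spindle_rate_per_min,
    sw_rate_per_min = sw_rate_per_min,
    spindle_amp_rms = spindle_amp_rms, sw_amp_rms = sw_amp_rms,
    env_mod_depth = env_mod_depth,
    resp_freq_hz = resp_freq_hz, cardiac_freq_hz = cardiac_freq_hz,
    resp_rate_var = resp_rate_var, resp_depth_var = resp_depth_var,
    cardiac_rate_var = cardiac_rate_var,
    one_over_f_exponent = one_over_f_exponent,
    bold_amp_mod = bold_amp_mod,
    bold_background_sd = bold_background_sd,
    hyp_dwell_s = hyp_dwell_s, epoch_s = epoch_s)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$duration_s, "s,", x$n_regions, "regions, TR",
      x$tr_s, "s, seed", x$seed, "\n")
  cat("  LF", sprintf("%.3f-%.3f", min(x$lf_freq_hz), max(x$lf_freq_hz)),
      "Hz; HF", sprintf("%.3f-%.3f", min(x$hf_freq_hz), max(x$hf_freq_hz)),
      "Hz\n")
  invisible(x)
}

# Seeded sub-stream helpers: each generator component draws from
# seed + offset so components are reproducible independently of call order.
.sub_rng <- function(seed, offset) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed((seed + offset) %% .Machine$integer.max)
  old
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Simulate a hypnogram with one falling-asleep and one waking transition
#'
#' Generates the stage trajectory W -> N1 -> N2 -> N3 -> N2 -> W in 30-s
#' epochs with configurable dwell times, emulating a nap run with continuous
#' N2/N3 sleep bracketed by wake.
#'
#' @param config a [sim_config()].
#' @return object of class `hypnogram`: list with `stages` (character,
#'   one per epoch) and `epoch_s`.
#' @export
simulate_hypnogram <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$duration_s < 20 * 60)
    stop("duration too short to fit a W-N1-N2-N3-N2-W trajectory (need >= 1200 s)")
  ep <- config$epoch_s
  n_ep <- floor(config$duration_s / ep)
  dwell <- config$hyp_dwell_s
  segs <- c("W", "N1", "N2", "N3", "N2", "W")
  if (is.null(dwell)) {
    prop <- c(2, 1, 2.5, 3, 1.5, 2) / 12
    dwell <- prop * n_ep * ep
  }
  if (length(dwell) != 6L)
    stop("hyp_dwell_s must give six dwell times (W, N1, N2, N3, N2, W)")
  ep_per <- round(dwell / ep)
  ep_per <- pmax(ep_per, 1L)
  # absorb rounding into the final wake segment
  ep_per[6] <- n_ep - sum(ep_per[1:5])
  if (ep_per[6] < 1L)
    stop("duration too short for the requested dwell times")
  stages <- rep(segs, times = ep_per)
  structure(list(stages = stages, epoch_s = ep), class = "hypnogram")
}

#' Construct a hypnogram from a stage vector
#' @param stages character vector of stage labels (W, N1, N2, N3, R).
#' @param epoch_s epoch length in seconds.
#' @return a `hypnogram` object.
#' @export
hypnogram <- function(stages, epoch_s = 30) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), c("W", "N1", "N2", "N3", "R"))
  if (length(bad))
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  structure(list(stages = stages, epoch_s = epoch_s), class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  r <- rle(x$stages)
  cat("<hypnogram>", length(x$stages), "epochs x", x$epoch_s, "s:",
      paste(sprintf("%s(%d)", r$values, r$lengths), collapse = " "), "\n")
  invisible(x)
}

#' Stage label at given times
#' @param hyp a `hypnogram`.
#' @param t_s numeric vector of times (seconds from recording start).
#' @return character vector of stage labels; times beyond the hypnogram get
#'   the last epoch's stage.
#' @export
stage_at <- function(hyp, t_s) {
  idx <- pmin(pmax(floor(t_s / hyp$epoch_s) + 1L, 1L), length(hyp$stages))
  hyp$stages[idx]
}
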