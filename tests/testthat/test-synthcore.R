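test_that("hypnogram trajectory covers all NREM stages with the right epoch count", {
  cfg <- sim_config(seed = 1, duration_s = 3600)
  hyp <- simulate_hypnogram(cfg)
  expect_length(hyp$stages, 120)                    # 3600 / 30
  expect_true(all(c("W", "N1", "N2", "N3") %in% hyp$stages))
  # one falling-asleep and one waking transition
  r <- rle(hyp$stages %in% c("N1", "N2", "N3"))
  expect_identical(sum(r$values), 1L)
  expect_identical(hyp$stages[1], "W")
  expect_identical(hyp$stages[120], "W")
})

test_that("hypnogram rejects durations too short for the trajectory", {
  cfg <- quick_config()
  cfg$duration_s <- 1100
  expect_error(simulate_hypnogram(cfg), "too short")
})

test_that("unknown stage labels are rejected", {
  expect_error(hypnogram(c("W", "N4")), "N4")
})

test_that("identical config yields bitwise-identical recordings", {
  cfg <- quick_config(seed = 7)
  r1 <- simulate_recording(cfg)
  r2 <- simulate_recording(cfg)
  expect_identical(r1$bold$values, r2$bold$values)
  expect_identical(r1$eeg, r2$eeg)
  expect_identical(r1$events_truth, r2$events_truth)
  expect_identical(r1$physio$resp, r2$physio$resp)
  expect_identical(r1$hypnogram$stages, r2$hypnogram$stages)
})

test_that("zero-gain BOLD is pure 1/f background: slope ~ -1, no band peaks", {
  g0 <- list(W = c(0, 0), N1 = c(0, 0), N2 = c(0, 0), N3 = c(0, 0),
             R = c(0, 0))
  cfg <- sim_config(seed = 2, duration_s = 3600, n_regions = 6,
                    stage_gain = g0)
  hyp <- simulate_hypnogram(cfg)
  bold <- simulate_bold(cfg, hyp)
  spec <- sliding_spectrogram(bold)
  m <- rowMeans(apply(spec$power, c(1, 3), mean))
  fit <- fit_one_over_f(spec$freqs_hz, m)
  expect_lt(abs(fit$slope - (-1)), 0.1)
  pk <- detect_band_peaks(spec$freqs_hz, fit)
  expect_false(pk$LF$detected)
  expect_false(pk$HF$detected)
})

test_that("doubling an oscillation gain quadruples that band's power", {
  mk <- function(g) {
    sg <- list(W = c(g, 0), N1 = c(g, 0), N2 = c(g, 0), N3 = c(g, 0),
               R = c(g, 0))
    cfg <- sim_config(seed = 3, duration_s = 3600, n_regions = 4,
                      stage_gain = sg, lf_freq_hz = rep(0.0577, 4),
                      hf_freq_hz = rep(0.1635, 4))
    hyp <- simulate_hypnogram(cfg)
    bold <- simulate_bold(cfg, hyp)
    spec <- sliding_spectrogram(bold)
    tr <- band_power_trace(spec, c(0.0577 - 0.01, 0.0577 + 0.01))
    mean(tr$values)
  }
  p1 <- mk(1)
  p2 <- mk(2)
  # background contributes to band power of both; compare increments
  p0 <- mk(0)
  expect_lt(abs((p2 - p0) / (p1 - p0) - 4), 4 * 0.1)
})

test_that("zero event rates give empty truth and pure-background EEG", {
  cfg <- quick_config(seed = 4,
                      spindle_rate_per_min = c(W = 0, N1 = 0, N2 = 0, N3 = 0, R = 0),
                      sw_rate_per_min = c(W = 0, N1 = 0, N2 = 0, N3 = 0, R = 0))
  hyp <- simulate_hypnogram(cfg)
  ee <- simulate_eeg(cfg, hyp)
  expect_identical(nrow(ee$events_truth), 0L)
})

test_that("truth spindle count in N2 matches the Poisson expectation", {
  counts <- vapply(1:4, function(seed) {
    cfg <- sim_config(seed = seed, duration_s = 3600)
    hyp <- simulate_hypnogram(cfg)
    ee <- simulate_eeg(cfg, hyp)
    tsp <- ee$events_truth[ee$events_truth$type == "spindle", ]
    sum(stage_at(hyp, tsp$onset_s) == "N2")
  }, numeric(1))
  n2_min <- sum(simulate_hypnogram(sim_config(1, 3600))$stages == "N2") / 2
  lambda <- 2 * n2_min * 4          # pooled over 4 runs
  expect_lt(abs(sum(counts) - lambda), 2 * sqrt(lambda))
})

test_that("excessive event rates are rejected for overlap", {
  cfg <- quick_config(sw_rate_per_min = c(W = 0, N1 = 0, N2 = 0, N3 = 40, R = 0))
  hyp <- simulate_hypnogram(cfg)
  expect_error(simulate_eeg(cfg, hyp), "rate too high")
})

test_that("truth spindle density is grouped by the infra-slow envelope", {
  # amplitude of the binned density at the envelope frequency must exceed
  # the level at nearby non-envelope frequencies, pooled over seeds
  amp_at <- function(x, t, f) Mod(sum(x * exp(-2i * pi * f * t)))
  on_f <- off_f <- 0
  for (seed in 1:5) {
    cfg <- sim_config(seed = seed, duration_s = 3600,
                      lf_freq_hz = rep(0.055, 12))
    hyp <- simulate_hypnogram(cfg)
    ee <- simulate_eeg(cfg, hyp)
    tsp <- ee$events_truth[ee$events_truth$type == "spindle", ]
    n2 <- which(hyp$stages == "N2")
    # restrict to the long N2 block so the stage gate does not leak in
    sel <- tsp$onset_s[stage_at(hyp, tsp$onset_s) == "N2"]
    b <- seq(min(n2 - 1) * 30, max(n2) * 30, by = 5)
    h <- graphics::hist(sel, breaks = b, plot = FALSE)$counts
    tm <- b[-length(b)] + 2.5
    on_f <- on_f + amp_at(h - mean(h), tm, 0.055)
    off_f <- off_f + (amp_at(h - mean(h), tm, 0.031) +
                      amp_at(h - mean(h), tm, 0.083)) / 2
  }
  expect_gt(on_f, off_f)
})

test_that("zero-variability physiology is strictly periodic at the set frequencies", {
  cfg <- quick_config(seed = 5, resp_rate_var = 0, resp_depth_var = 0,
                      cardiac_rate_var = 0)
  ph <- simulate_physio(cfg)
  sr <- physio_spectrum(ph$resp, ph$fs)
  expect_equal(sr$peak_freq_hz, 0.25, tolerance = 1e-6)
  sc <- physio_spectrum(ph$cardiac, ph$fs)
  expect_equal(sc$peak_freq_hz, 1.0, tolerance = 1e-6)
  # strict periodicity: one period repeats exactly
  p <- round(ph$fs / 0.25)
  expect_lt(max(abs(ph$resp[1:p] - ph$resp[(p + 1):(2 * p)])), 1e-9)
})

test_that("physio frequencies above Nyquist are rejected", {
  cfg <- quick_config(physio_fs_hz = 1.6)
  expect_error(simulate_physio(cfg), "Nyquist")
})

test_that("oscillation frequencies above the BOLD Nyquist are rejected", {
  expect_error(sim_config(hf_freq_hz = rep(0.3, 3), n_regions = 3),
               "Nyquist")
})
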