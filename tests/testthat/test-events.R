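test_that("sub-threshold noise yields no spindles; short recordings are rejected", {
  set.seed(1)
  x <- rnorm(250 * 120)
  expect_identical(nrow(detect_spindles(x, 250)), 0L)
  expect_error(detect_spindles(rnorm(250 * 30), 250), "60 s")
  expect_error(detect_spindles(rnorm(5000), 50), "100 Hz")
})

test_that("one injected sigma burst is found with accurate onset and duration", {
  set.seed(2)
  fs <- 250
  x <- rnorm(fs * 120) * 0.2
  sig_rms <- sd(signal::filtfilt(signal::butter(4, c(11, 16) / (fs / 2),
                                                "pass"), x))
  k <- seq_len(fs * 1)                       # 1.0-s burst at t = 5 s
  x[5 * fs + k] <- x[5 * fs + k] + 5 * sig_rms * sin(2 * pi * 13 * k / fs)
  ev <- detect_spindles(x, fs)
  expect_identical(nrow(ev), 1L)
  expect_lt(abs(ev$onset_s - 5.0), 0.2)
  expect_gte(ev$duration_s, 0.6)
  expect_lte(ev$duration_s, 1.4)
})

test_that("spindle detection is invariant to global amplitude rescaling", {
  cfg <- quick_config(seed = 8)
  hyp <- simulate_hypnogram(cfg)
  ee <- simulate_eeg(cfg, hyp)
  e1 <- detect_spindles(ee$eeg, ee$fs)
  e2 <- detect_spindles(ee$eeg * 37, ee$fs)
  expect_equal(e1$onset_s, e2$onset_s)
  expect_equal(e1$duration_s, e2$duration_s)
})

test_that("flat input yields no slow waves; one biphasic wave yields one event", {
  expect_identical(nrow(detect_slow_waves(rep(0, 250 * 90), 250)), 0L)
  set.seed(3)
  fs <- 250
  x <- rnorm(fs * 120) * 0.2
  xf <- signal::filtfilt(signal::butter(4, c(0.5, 4) / (fs / 2), "pass"), x)
  amp <- 6 * sd(xf)
  k <- seq_len(round(1.2 * fs))              # 1.2-s biphasic wave at t = 30 s
  x[30 * fs + k] <- x[30 * fs + k] - amp * sin(2 * pi * (k - 1) / length(k))
  ev <- detect_slow_waves(x, fs)
  expect_identical(nrow(ev), 1L)
  expect_lt(abs(ev$onset_s - 30.0), 0.3)
  expect_lt(ev$amplitude, 0)
})

test_that("binned activity integrates event-bin overlap exactly", {
  ev <- data.frame(onset_s = 10.0, duration_s = 1.0, type = "spindle",
                   channel = "EEG1", amplitude = 1)
  act <- bin_activity(ev, bin_s = 2.08, span = c(0, 20.8))
  # event [10, 11) straddles bins [8.32, 10.40) and [10.40, 12.48)
  expect_equal(act$values[5], 0.40, tolerance = 1e-12)
  expect_equal(act$values[6], 0.60, tolerance = 1e-12)
  expect_equal(sum(act$values), 1.0, tolerance = 1e-12)
})

test_that("activity conservation: bin totals equal total event seconds", {
  cfg <- quick_config(seed = 9)
  hyp <- simulate_hypnogram(cfg)
  ee <- simulate_eeg(cfg, hyp)
  act <- bin_activity(ee$events_truth, span = c(0, cfg$duration_s + 4.16))
  expect_equal(sum(act$values), sum(ee$events_truth$duration_s),
               tolerance = 1e-9)
  empty <- bin_activity(ee$events_truth[0, ], span = c(0, 100))
  expect_true(all(empty$values == 0))
})

test_that("Hamming aggregation is a weighted mean with the expected geometry", {
  const <- structure(list(values = rep(3.7, 120), bin_s = 2.08,
                          bin_starts_s = (0:119) * 2.08),
                     class = "activity_trace")
  agg <- hamming_aggregate(const)
  expect_true(all(abs(agg$values - 3.7) < 1e-12))
  # a bin at a window's center outweighs the same bin at its edge
  mk <- function(pos) {
    v <- numeric(120)
    v[pos] <- 1
    structure(list(values = v, bin_s = 2.08, bin_starts_s = (0:119) * 2.08),
              class = "activity_trace")
  }
  ctr <- hamming_aggregate(mk(60))$values[36]   # bin 60 centers window 36
  edg <- hamming_aggregate(mk(60))$values[60]   # same bin at window 60's edge
  expect_gt(ctr, edg)
  # linearity: aggregation commutes with trace addition
  a <- mk(30)
  b <- mk(80)
  ab <- mk(30)
  ab$values <- a$values + b$values
  expect_equal(hamming_aggregate(ab)$values,
               hamming_aggregate(a)$values + hamming_aggregate(b)$values)
})

test_that("Hamming aggregation matches a direct convolution oracle", {
  set.seed(4)
  v <- rpois(150, 1) * 0.5
  tr <- structure(list(values = v, bin_s = 2.08, bin_starts_s = (0:149) * 2.08),
                  class = "activity_trace")
  agg <- hamming_aggregate(tr)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:49) / 49)
  direct <- vapply(0:(150 - 50), function(s)
    sum(w * v[(s + 1):(s + 50)]) / sum(w), numeric(1))
  expect_equal(agg$values, direct, tolerance = 1e-12)
})

test_that("EEG band power separates sigma and delta tones", {
  fs <- 250
  t <- (0:(fs * 240 - 1)) / fs
  sig13 <- sin(2 * pi * 13 * t)
  sigma <- eeg_band_power_trace(sig13, fs, c(11, 16), window_s = 20.8,
                                step_s = 10.4)
  delta <- eeg_band_power_trace(sig13, fs, c(0.5, 4), window_s = 20.8,
                                step_s = 10.4)
  expect_gt(mean(sigma$values) / mean(delta$values), 100)
  sig1 <- sin(2 * pi * 1 * t)
  sigma1 <- eeg_band_power_trace(sig1, fs, c(11, 16), window_s = 20.8,
                                 step_s = 10.4)
  delta1 <- eeg_band_power_trace(sig1, fs, c(0.5, 4), window_s = 20.8,
                                 step_s = 10.4)
  expect_gt(mean(delta1$values) / mean(sigma1$values), 100)
})

test_that("sigma power tracks truth spindle density on synthetic N2 sleep", {
  cfg <- sim_config(seed = 10, duration_s = 3600)
  hyp <- simulate_hypnogram(cfg)
  ee <- simulate_eeg(cfg, hyp)
  sig <- eeg_band_power_trace(ee$eeg, ee$fs, c(11, 16))
  act <- hamming_aggregate(bin_activity(
    ee$events_truth[ee$events_truth$type == "spindle", ],
    span = c(0, length(sig$values) * 2.08 + 104 - 2.08)))
  n <- min(length(sig$values), length(act$values))
  expect_gt(cor(sig$values[seq_len(n)], act$values[seq_len(n)]), 0.5)
})
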