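test_that("window count and centers follow the sliding contract", {
  ts <- region_ts(matrix(rnorm(900), 900, 1), tr_s = 2.08)
  spec <- sliding_spectrogram(ts, 50, 1)
  expect_identical(dim(spec$power)[2], 851L)        # floor((900-50)/1)+1
  expect_equal(spec$window_centers_s[1], (49 / 2) * 2.08)
  expect_equal(diff(spec$window_centers_s[1:2]), 2.08)
  expect_true(all(spec$power >= 0) && all(is.finite(spec$power)))
  expect_error(sliding_spectrogram(region_ts(matrix(rnorm(40), 40, 1), 2.08)),
               "shorter than one analysis window")
})

test_that("a unit sinusoid at a bin frequency yields band power 0.5 at that bin", {
  tr <- 2.08
  f <- 5 / (50 * tr)                 # exactly bin 5
  t <- (0:599) * tr
  ts <- region_ts(matrix(sin(2 * pi * f * t + 0.7), ncol = 1), tr_s = tr)
  spec <- sliding_spectrogram(ts)
  peaks <- apply(spec$power[, , 1], 2, which.max)
  expect_true(all(peaks == 5L))
  expect_equal(mean(spec$power[5, , 1]), 0.5, tolerance = 0.02)
})

test_that("windowed Parseval identity holds between frequency and time domain", {
  set.seed(42)
  x <- rnorm(200)
  ts <- region_ts(matrix(x, ncol = 1), tr_s = 2.08)
  spec <- sliding_spectrogram(ts)
  N <- 50
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(N - 1)) / (N - 1))
  for (i in c(1, 75, 151)) {
    seg <- x[i:(i + N - 1)]
    seg <- seg - mean(seg)
    # time-domain total power, DC term removed, taper-sum normalisation
    direct <- (N * sum((w * seg)^2) - sum(w * seg)^2) / sum(w)^2
    expect_equal(sum(spec$power[, i, 1]), direct, tolerance = 1e-10)
  }
})

test_that("stage averaging is a set operation with explicit absences", {
  set.seed(1)
  ts <- region_ts(matrix(rnorm(400), 400, 1), tr_s = 2.08)
  spec <- sliding_spectrogram(ts)
  hyp <- hypnogram(rep("N2", 40))
  av <- stage_average_spectrum(spec, hyp, "N2")
  expect_true(av$available)
  expect_equal(av$spectrum[, 1], rowMeans(spec$power[, , 1]))
  # permuting window order leaves the average unchanged
  p <- sample(dim(spec$power)[2])
  spec_p <- spec
  spec_p$power <- spec$power[, p, , drop = FALSE]
  spec_p$window_centers_s <- spec$window_centers_s[p]
  av_p <- stage_average_spectrum(spec_p, hyp, "N2")
  expect_equal(av_p$spectrum, av$spectrum)
  # absent stage is reported, not silently zero
  miss <- stage_average_spectrum(spec, hyp, "N3")
  expect_false(miss$available)
  expect_match(miss$reason, "N3")
})

test_that("1/f fit recovers exact power laws", {
  freqs <- (1:25) / 104
  fit <- fit_one_over_f(freqs, 3 / freqs)
  expect_equal(fit$slope, -1, tolerance = 1e-10)
  expect_lt(max(abs(fit$residual)), 1e-10)
  flat <- fit_one_over_f(freqs, rep(2, 25))
  expect_equal(flat$slope, 0, tolerance = 1e-10)
})

test_that("a spectral bump above the 1/f trend is localised to its frequency", {
  freqs <- (1:25) / 104
  bump <- exp(-(freqs - 0.055)^2 / (2 * 0.004^2))
  pw <- 0.5 / freqs * (1 + 4 * bump)
  fit <- fit_one_over_f(freqs, pw)
  pk <- detect_band_peaks(freqs, fit)
  expect_true(pk$LF$detected)
  expect_lt(abs(pk$LF$peak_freq_hz - 0.055), 1 / 104 + 1e-12)
  expect_false(pk$HF$detected)
})

test_that("flat residuals produce no peaks", {
  freqs <- (1:25) / 104
  fit <- fit_one_over_f(freqs, 1 / freqs)
  pk <- detect_band_peaks(freqs, fit)
  expect_false(pk$LF$detected)
  expect_false(pk$HF$detected)
})

test_that("band power trace averages band bins and warns on sub-bin bands", {
  set.seed(2)
  ts <- region_ts(matrix(rnorm(300), 300, 2), tr_s = 2.08)
  spec <- sliding_spectrogram(ts)
  band <- c(0.04, 0.07)
  tr <- band_power_trace(spec, band)
  idx <- which(spec$freqs_hz >= band[1] & spec$freqs_hz <= band[2])
  expect_equal(unname(tr$values[10, 2]), mean(spec$power[idx, 10, 2]))
  expect_warning(band_power_trace(spec, c(0.051, 0.053)), "nearest bin")
})

test_that("percent power change matches its arithmetic definition", {
  hyp <- two_block_hyp(40, 40)
  ws <- window_stages(make_trace(matrix(0, 1105, 1)), hyp)
  v <- ifelse(ws == "W", 1.0, ifelse(ws == "N2", 3.5, 2.0))
  tr <- make_trace(matrix(v, ncol = 1))
  pc <- percent_power_change(tr, hyp, target_stages = "N2")
  expect_equal(unname(pc), 250)
  # identity: no change
  tr0 <- make_trace(matrix(rep(1, 1105), ncol = 1))
  expect_equal(unname(percent_power_change(tr0, hyp, target_stages = "N2")), 0)
  # invariance under global rescaling of the input series (power x c^2)
  tr_s <- tr
  tr_s$values <- tr$values * 7.3
  expect_equal(percent_power_change(tr_s, hyp, target_stages = "N2"),
               percent_power_change(tr, hyp, target_stages = "N2"))
})

test_that("percent change rejects non-positive baselines and thin stages", {
  hyp <- two_block_hyp(40, 40)
  tr <- make_trace(matrix(0, 1105, 1))
  expect_error(percent_power_change(tr, hyp, target_stages = "N2"),
               "non-positive")
  hyp2 <- hypnogram(c(rep("W", 2), rep("N2", 78)))
  tr2 <- make_trace(matrix(1, 1105, 1))
  expect_error(percent_power_change(tr2, hyp2, target_stages = "N2"),
               "clean windows")
})

test_that("a stage-gain step appears in the band trace near the step time", {
  cfg <- sim_config(seed = 6, duration_s = 2400, n_regions = 1,
                    lf_freq_hz = 0.0577, hf_freq_hz = 0.1635,
                    hyp_dwell_s = c(600, 30, 600, 570, 300, 300))
  hyp <- simulate_hypnogram(cfg)
  bold <- simulate_bold(cfg, hyp)
  spec <- sliding_spectrogram(bold)
  tr <- band_power_trace(spec, c(0.0477, 0.0677))
  v <- tr$values[, 1]
  lo <- mean(v[tr$window_centers_s < 400])
  hi <- mean(v[tr$window_centers_s > 800 & tr$window_centers_s < 1100])
  half <- (lo + hi) / 2
  cross <- tr$window_centers_s[which(v > half & tr$window_centers_s > 400)[1]]
  # the W->N1 gain step at 600 s appears within half a window of the step
  expect_lt(abs(cross - 600), 52 + 10)
})
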