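make_tone <- function(f, fs = 400, dur = 10, channel = "ecg") {
  tt <- (0:(fs * dur - 1)) / fs
  raw_recording(channel, fs, sin(2 * pi * f * tt))
}

test_that("band-pass keeps the passband and rejects baseline wander", {
  lo <- bandpass_filter(make_tone(0.2))
  expect_lt(20 * log10(stats::sd(lo$samples) / stats::sd(make_tone(0.2)$samples)),
            -20)
  mid <- bandpass_filter(make_tone(10))
  gain_db <- 20 * log10(stats::sd(mid$samples) / stats::sd(make_tone(10)$samples))
  expect_lt(abs(gain_db), 1)
  z <- bandpass_filter(raw_recording("ecg", 400, rep(0, 4000)))
  expect_true(all(abs(z$samples) < 1e-12))
  expect_equal(length(mid$samples), 4000)
  expect_error(bandpass_filter(make_tone(10), high_hz = 300), "Nyquist")
  # passband idempotence: double application changes passband RMS < 2%
  twice <- bandpass_filter(mid)
  expect_lt(abs(stats::sd(twice$samples) / stats::sd(mid$samples) - 1), 0.02)
})

test_that("notch removes the powerline tone and little else", {
  hum <- notch_filter(make_tone(50))
  expect_lte(stats::sd(hum$samples) / stats::sd(make_tone(50)$samples), 0.1)
  dc <- notch_filter(raw_recording("ecg", 400, rep(3, 4000)))
  expect_true(all(abs(dc$samples - 3) < 1e-9))
  sig <- notch_filter(make_tone(10))
  expect_lt(abs(stats::sd(sig$samples) / stats::sd(make_tone(10)$samples) - 1),
            0.1)
  expect_error(notch_filter(make_tone(10), f0_hz = 250), "Nyquist")
})

test_that("GSR resampling hits the target grid and preserves slow content", {
  g <- raw_recording("gsr", 201, rep(5, 201 * 60))
  g4 <- resample_gsr(g)
  expect_equal(g4$rate_hz, 4)
  expect_length(g4$samples, 240)
  expect_true(all(abs(g4$samples - 5) < 1e-9))
  tt <- (0:(201 * 600 - 1)) / 201
  gs <- resample_gsr(raw_recording("gsr", 201, 5 + sin(2 * pi * 0.05 * tt)))
  expect_length(gs$samples, 2400)
  amp <- (max(gs$samples) - min(gs$samples)) / 2
  expect_lt(abs(amp - 1), 0.05)
  expect_lt(abs(mean(gs$samples) - 5) / 5, 0.01)
  expect_error(resample_gsr(g, target_hz = 500), "below")
})

test_that("R-peak detection recovers planted beats on realistic RR", {
  set.seed(8)
  rr <- simulate_rr_series(default_state_effects()$neutral, 240)
  ecg <- synthesize_ecg(rr, 400)
  planted <- attr(ecg, "beat_times_s")
  ann <- detect_r_peaks(notch_filter(bandpass_filter(ecg)))
  det <- ann$event_times_s
  sens <- mean(vapply(planted, function(t) min(abs(det - t)) <= 0.010, TRUE))
  prec <- mean(vapply(det, function(t) min(abs(planted - t)) <= 0.010, TRUE))
  expect_gte(sens, 0.99)
  expect_gte(prec, 0.99)
  expect_true(all(diff(det) >= 0.25))
  # polarity inversion changes nothing
  inv <- raw_recording("ecg", 400, -ecg$samples)
  expect_length(detect_r_peaks(inv)$event_times_s, length(det))
  expect_error(detect_r_peaks(raw_recording("ecg", 400, rep(0, 2000))),
               "too-short")
})

test_that("pulse onsets track planted beats and flat input errors", {
  set.seed(9)
  rr <- simulate_rr_series(default_state_effects()$neutral, 120)
  ef <- state_effect(pulse_amp_mean = 0.8, pulse_amp_sd = 0.05)
  bvp <- synthesize_bvp(rr, ef, 201)
  ann <- detect_pulses(bvp)
  pl_on <- c(0, cumsum(rr)[-length(rr)])
  hit <- mean(vapply(pl_on[-1], function(t)
    min(abs(ann$onset_times_s - t)) <= 0.010, TRUE))
  expect_gte(hit, 0.98)
  expect_length(ann$onset_times_s, length(ann$peak_times_s))
  expect_true(all(ann$amplitudes >= 0))
  expect_error(detect_pulses(raw_recording("bvp", 201, rep(1, 2000))),
               "too-short")
})

test_that("EDA decomposition conserves the signal and finds planted SCRs", {
  # drift-only: phasic residual is a sliver of the signal
  tt <- (0:(4 * 600 - 1)) / 4
  ramp <- raw_recording("gsr", 4, 5 + 0.1 * tt / 60)
  eda <- decompose_eda(ramp)
  expect_lt(sqrt(mean(eda$phasic^2)) / sqrt(mean(ramp$samples^2)), 0.02)
  expect_equal(eda$tonic + eda$phasic, ramp$samples)
  # zero signal
  z <- decompose_eda(raw_recording("gsr", 4, rep(0, 400)))
  expect_true(all(z$tonic == 0) && all(z$phasic == 0))
  expect_equal(nrow(z$scr_events), 0)
  # planted 4 events/min at 0.5 uS recovered within 10% on average
  ratios <- vapply(1:4, function(s) {
    set.seed(s)
    ef <- state_effect(scr_rate_per_min = 4, scr_amp_mean = 0.5,
                       tonic_level = 5)
    g <- synthesize_gsr(ef, 600, 201)
    ed <- decompose_eda(resample_gsr(g))
    nrow(ed$scr_events) / nrow(attr(g, "scr_events"))
  }, numeric(1))
  expect_gte(mean(ratios), 0.9)
  expect_lte(mean(ratios), 1.1)
  expect_error(decompose_eda(raw_recording("gsr", 4, rep(1, 100))), "60 s")
})

test_that("SCR events report sensible amplitudes and rise times", {
  ef1 <- state_effect(scr_rate_per_min = 0, scr_amp_mean = 0, tonic_level = 5,
                      tonic_drift_per_min = 0)
  g <- synthesize_gsr(ef1, 120, 201, noise_sd = 0)
  g$samples <- transfeat:::add_scr_events(g$samples, 60, 0.5, 201)
  eda <- decompose_eda(resample_gsr(g))
  expect_equal(nrow(eda$scr_events), 1)
  expect_lt(abs(eda$scr_events$amplitude - 0.5), 0.1)
  expect_lt(abs(eda$scr_events$rise_time_s - 1.18), 0.5)
  expect_gt(eda$scr_events$rise_time_s, 0)
})

test_that("window grid matches the printed counts and brute force", {
  expect_equal(nrow(make_windows(c(0, 240))), 181)
  expect_equal(nrow(make_windows(c(0, 60))), 1)
  expect_equal(nrow(make_windows(c(0, 62))), 3)
  expect_error(make_windows(c(0, 59)), "empty-grid")
  set.seed(123)
  for (i in 1:1000) {
    win <- sample(5:90, 1)
    len <- win + sample(0:300, 1)
    step <- sample(1:10, 1)
    expect_equal(nrow(make_windows(c(0, len), win, step)),
                 brute_window_count(len, win, step))
  }
  wg <- make_windows(c(100, 180), 60, 7)
  expect_true(all(wg$end_s <= 180))
  expect_true(all(diff(wg$start_s) == 7))
})
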