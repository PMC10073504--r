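test_that("time-domain HRV statistics match hand arithmetic", {
  h <- hrv_time(c(0.8, 0.9, 0.8, 0.9))
  expect_equal(unname(h["MEANRR"]), 0.85)
  expect_equal(unname(h["RMSSD"]), 0.1)
  expect_equal(unname(h["NN50"]), 3)
  expect_equal(unname(h["PNN50"]), 1)
  expect_equal(unname(h["HR"]), 60 / 0.85, tolerance = 1e-10)
  expect_equal(unname(h["SDNN"]), stats::sd(c(0.8, 0.9, 0.8, 0.9)))
  const <- hrv_time(rep(0.8, 20))
  expect_true(all(const[c("SDNN", "RMSSD", "NN50", "PNN50")] == 0))
  expect_equal(unname(hrv_time(rep(0.75, 10))["HR"]), 80)
  expect_true(all(is.na(hrv_time(c(0.8, 0.9)))))
  # NN50 counts strictly greater than 50 ms
  expect_equal(unname(hrv_time(c(0.80, 0.85, 0.80, 0.85))["NN50"]), 0)
  expect_equal(unname(hrv_time(c(0.80, 0.851, 0.80))["NN50"]), 2)
})

test_that("HRV statistics are scale-equivariant", {
  set.seed(5)
  rr <- 0.8 + 0.05 * stats::rnorm(80)
  for (c0 in c(0.5, 2)) {
    a <- hrv_time(rr); b <- hrv_time(rr * c0)
    expect_equal(unname(b["MEANRR"]), unname(a["MEANRR"]) * c0)
    expect_equal(unname(b["SDNN"]), unname(a["SDNN"]) * c0)
    expect_equal(unname(b["RMSSD"]), unname(a["RMSSD"]) * c0)
    expect_equal(unname(b["HR"]), unname(a["HR"]) / c0)
  }
  # SampEn with relative tolerance is invariant to affine maps
  x <- stats::rnorm(150)
  expect_equal(sample_entropy(3 * x + 7), sample_entropy(x))
})

test_that("spectral band powers localise the planted modulation", {
  set.seed(2)
  ef_hf <- state_effect(mean_rr_s = 0.8, rr_sd_s = 0, rr_lf_amp_s = 0,
                        rr_hf_amp_s = 0.05)
  rr <- simulate_rr_series(ef_hf, 62)
  f <- hrv_freq(rr[cumsum(rr) <= 60])
  expect_gt(f[["HF"]], 10 * f[["LF"]])
  ef_lf <- state_effect(mean_rr_s = 0.8, rr_sd_s = 0, rr_lf_amp_s = 0.05,
                        rr_hf_amp_s = 0)
  rr <- simulate_rr_series(ef_lf, 62)
  f2 <- hrv_freq(rr[cumsum(rr) <= 60])
  expect_gt(f2[["LFHF"]], 1)
  fc <- hrv_freq(rep(0.8, 75))
  expect_equal(unname(fc[c("VLF", "LF", "HF")]), c(0, 0, 0))
  expect_true(is.na(fc[["LFHF"]]))
})

test_that("band powers are non-negative and bounded by tachogram variance", {
  # stationary tachograms (sinusoidal modulation + white beat noise): the
  # Parseval bound is a property of the estimator for stationary input; a
  # wandering baseline makes any tapered estimate a *local* variance
  set.seed(6)
  for (i in 1:30) {
    mean_rr <- stats::runif(1, 0.6, 1.1)
    lf <- stats::runif(1, 0, 0.03)
    hf <- stats::runif(1, 0, 0.03)
    sdw <- stats::runif(1, 0.005, 0.03)
    rr <- numeric(0); t <- 0
    while (t < 60) {
      r <- mean_rr + lf * sin(2 * pi * 0.1 * t) + hf * sin(2 * pi * 0.25 * t) +
        stats::rnorm(1, 0, sdw)
      r <- max(r, 0.3); rr <- c(rr, r); t <- t + r
    }
    f <- hrv_freq(rr)
    expect_true(all(f[c("VLF", "LF", "HF")] >= 0))
    tb <- cumsum(rr)
    y <- stats::spline(tb, rr, xout = seq(tb[1], tb[length(tb)], by = 0.25))$y
    y <- stats::resid(stats::lm(y ~ seq_along(y)))
    expect_lte(sum(f[c("VLF", "LF", "HF")]), stats::var(y) * 1.05)
  }
})

test_that("sample entropy follows its conventions and the brute-force oracle", {
  expect_equal(sample_entropy(rep(3, 50)), 0)
  per <- rep(1:3, 20)
  expect_equal(sample_entropy(per), 0)  # all m-matches extend
  expect_true(is.na(sample_entropy(c(1, 2, 3))))
  set.seed(7)
  for (i in 1:10) {
    n <- sample(30:200, 1)
    x <- stats::rnorm(n)
    r <- 0.2 * stats::sd(x)
    expect_equal(sample_entropy(x), brute_sampen(x, 2, r), tolerance = 1e-10)
  }
})

test_that("multiscale entropy coarse-grains as defined", {
  set.seed(8)
  x <- as.numeric(stats::arima.sim(list(ar = 0.7), 150, sd = 0.02)) + 0.8
  m <- multiscale_entropy(x)
  expect_named(m, paste0("MSE", 1:5))
  expect_equal(m[["MSE1"]], sample_entropy(x))
  r <- 0.2 * stats::sd(x)
  for (tau in 2:5) {
    ncg <- floor(length(x) / tau)
    cg <- colMeans(matrix(x[seq_len(ncg * tau)], nrow = tau))
    expect_equal(m[[paste0("MSE", tau)]], brute_sampen(cg, 2, r),
                 tolerance = 1e-10)
  }
  expect_true(all(multiscale_entropy(rep(0.8, 100)) == 0))
  expect_true(is.na(multiscale_entropy(stats::rnorm(12))[["MSE5"]]))
})

test_that("BVP window features follow their definitions", {
  peaks <- seq(0.5, 59.5, by = 0.8)
  onsets <- peaks - 0.25
  n <- length(peaks)
  ann <- beat_annotations(event_times_s = peaks, onset_times_s = onsets,
                          peak_times_s = peaks,
                          amplitudes = rep(1, n),
                          widths_s = c(diff(onsets), NA),
                          peak_values = rep(1.1, n))
  b <- bvp_features(ann, c(0, 60))
  expect_equal(b[["STDPA"]], 0)
  expect_equal(b[["MAXPA"]], 1)
  expect_equal(b[["MEANPA"]], 1)
  expect_equal(b[["HIGH"]], 1.1)
  expect_equal(b[["MEANRR"]], 0.8, tolerance = 1e-10)
  expect_equal(b[["PR"]], 75, tolerance = 1e-10)
  expect_equal(b[["WIDTH"]], 0.8, tolerance = 1e-10)
  expect_equal(b[["H_W"]], 1 / 0.8, tolerance = 1e-10)
  # identical interval series gives the ECG SDNN
  set.seed(9)
  rr <- 0.8 + 0.04 * stats::rnorm(70)
  pk <- 0.3 + cumsum(rr)
  ann2 <- beat_annotations(event_times_s = pk, onset_times_s = pk - 0.2,
                           peak_times_s = pk, amplitudes = rep(1, length(pk)),
                           widths_s = c(diff(pk), NA),
                           peak_values = rep(1, length(pk)))
  win <- c(0, pk[length(pk)] + 1)
  expect_equal(bvp_features(ann2, win)[["SDNN"]],
               unname(hrv_time(diff(pk))["SDNN"]))
})

test_that("GSR window features follow their definitions", {
  n <- 240  # 60 s at 4 Hz
  eda <- structure(list(rate_hz = 4, t0_s = 0, tonic = rep(2.5, n),
                        phasic = rep(0, n),
                        scr_events = data.frame(onset_s = numeric(0),
                                                peak_s = numeric(0),
                                                amplitude = numeric(0),
                                                rise_time_s = numeric(0))),
                   class = "eda_components")
  g <- gsr_features(eda, c(0, 60))
  expect_equal(g[["MEANT"]], 2.5)
  expect_equal(g[["STDT"]], 0)
  expect_equal(g[["NUMP"]], 0)
  expect_true(all(g[c("MAXPA", "MEANPA", "STDPA", "MEANPR", "STDPR")] == 0))
  expect_equal(g[["AUCT"]], 2.5 * (n - 1) / 4, tolerance = 1e-10)
  # one event
  eda$scr_events <- data.frame(onset_s = 10, peak_s = 11.2, amplitude = 0.5,
                               rise_time_s = 1.2)
  g1 <- gsr_features(eda, c(0, 60))
  expect_equal(g1[["NUMP"]], 1)
  expect_equal(g1[["MAXPA"]], 0.5)
  expect_equal(g1[["MEANPA"]], 0.5)
  expect_equal(g1[["MEANPR"]], 1.2)
  expect_equal(g1[["STDPA"]], 0)
  expect_equal(g1[["STDPR"]], 0)
})

test_that("the registry defines exactly the 39 canonical features", {
  reg <- feature_registry()
  expect_length(reg$ecg, 15)
  expect_length(reg$bvp, 12)
  expect_length(reg$gsr, 12)
  expect_length(reg$all, 39)
  expect_false(anyDuplicated(reg$all) > 0)
  expect_equal(unname(feature_signal_group(c("SDNN_ECG", "PR_BVP", "PSD_GSR"))),
               c("ECG", "BVP", "GSR"))
  expect_error(feature_signal_group("NOPE"), "unknown")
})

test_that("a 240-s segment yields the full 181-window feature block", {
  tl <- session_timeline(data.frame(label = "neutral", start_s = 0,
                                    end_s = 240))
  cfg <- cohort_sim_config(n_subjects = 1, seed = 21, timeline = tl)
  co <- simulate_cohort(cfg)
  fm <- suppressMessages(extract_feature_matrix(co))
  expect_equal(nrow(fm), 181)
  expect_true(all(feature_registry()$all %in% names(fm)))
  expect_false(anyNA(as.matrix(fm[, feature_registry()$all])))
})

test_that("feature extraction is deterministic and windows stay in segments", {
  cfg <- cohort_sim_config(n_subjects = 2, seed = 31,
                           timeline = short_timeline(65))
  co <- simulate_cohort(cfg)
  fm1 <- suppressMessages(extract_feature_matrix(co))
  fm2 <- suppressMessages(extract_feature_matrix(co))
  expect_identical(fm1, fm2)
  expect_equal(sort(unique(fm1$segment)), 1:6)
  # 65-s segments hold 6 windows each
  expect_equal(nrow(fm1), 2 * 6 * 6)
  seg_start <- short_timeline(65)$start_s[fm1$segment]
  expect_true(all(fm1$window_start_s >= seg_start))
  expect_true(all(fm1$window_start_s + 60 <= seg_start + 65))
})
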