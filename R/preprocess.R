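# Zero-phase filtering with reflection padding so edges carry no transient
# and a constant input is returned unchanged (DC handled via mean removal by
# callers that need it).
zero_phase <- function(filt, x, pad_s, rate_hz) {
  n <- length(x)
  pad <- min(n - 1L, max(8L, round(pad_s * rate_hz)))
  if (pad < 1L) return(signal::filtfilt(filt, x))
  front <- 2 * x[1] - x[(pad + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(filt, c(front, x, back))
  y[(pad + 1L):(pad + n)]
}

#' Butterworth band-pass filter (zero phase)
#'
#' 4th-order high-pass and low-pass Butterworth sections in cascade, applied
#' forward-backward so event times are not shifted. Intended for ECG and BVP
#' (the defaults are the 1-40 Hz conditioning band).
#'
#' @param rec a `raw_recording` with channel `ecg` or `bvp`.
#' @param low_hz,high_hz cut-off frequencies, Hz; must satisfy
#'   `high_hz < rate/2`.
#' @param order filter order per edge.
#' @return A filtered `raw_recording` of the same length and rate.
#' @export
bandpass_filter <- function(rec, low_hz = 1, high_hz = 40, order = 4) {
  stopifnot(inherits(rec, "raw_recording"))
  if (!rec$channel %in% c("ecg", "bvp"))
    stop("bandpass_filter expects an ecg or bvp recording")
  nyq <- rec$rate_hz / 2
  if (high_hz >= nyq || low_hz >= nyq || low_hz <= 0 || high_hz <= low_hz)
    stop("cut-offs must satisfy 0 < low < high < Nyquist")
  x <- rec$samples - mean(rec$samples)
  hp <- signal::butter(order, low_hz / nyq, type = "high")
  lp <- signal::butter(order, high_hz / nyq, type = "low")
  y <- zero_phase(lp, zero_phase(hp, x, 3 / low_hz, rec$rate_hz),
                  0.5, rec$rate_hz)
  out <- raw_recording(rec$channel, rec$rate_hz, y, rec$t0_s)
  out
}

#' Notch filter for powerline interference (zero phase)
#'
#' Second-order IIR notch (pole radius from the quality factor), DC gain 1,
#' applied forward-backward.
#'
#' @param rec a `raw_recording`.
#' @param f0_hz notch frequency, Hz (default 50).
#' @param q quality factor; bandwidth = `f0_hz / q`.
#' @return A filtered `raw_recording` of the same length and rate.
#' @export
notch_filter <- function(rec, f0_hz = 50, q = 30) {
  stopifnot(inherits(rec, "raw_recording"))
  nyq <- rec$rate_hz / 2
  if (f0_hz >= nyq || f0_hz <= 0) stop("f0_hz must be in (0, Nyquist)")
  w0 <- 2 * pi * f0_hz / rec$rate_hz
  bw <- f0_hz / q
  r <- exp(-pi * bw / rec$rate_hz)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  g <- sum(a) / sum(b)  # unit gain at DC
  filt <- signal::Arma(b = g * b, a = a)
  m <- mean(rec$samples)
  y <- zero_phase(filt, rec$samples - m, 2 / bw, rec$rate_hz) + m
  raw_recording(rec$channel, rec$rate_hz, y, rec$t0_s)
}

#' Downsample a GSR recording
#'
#' Anti-alias low-pass (4th-order Butterworth at 0.8 x target Nyquist, zero
#' phase) followed by linear interpolation onto the target grid.
#'
#' @param rec a `raw_recording` with channel `gsr`.
#' @param target_hz output rate, Hz (default 4; must be below the input rate).
#' @return A `raw_recording` at `target_hz` covering the same span.
#' @export
resample_gsr <- function(rec, target_hz = 4) {
  stopifnot(inherits(rec, "raw_recording"))
  if (rec$channel != "gsr") stop("resample_gsr expects a gsr recording")
  if (target_hz >= rec$rate_hz) stop("target_hz must be below the input rate")
  cutoff <- 0.8 * target_hz / 2
  lp <- signal::butter(4, cutoff / (rec$rate_hz / 2), type = "low")
  m <- mean(rec$samples)
  y <- zero_phase(lp, rec$samples - m, 2 / cutoff, rec$rate_hz) + m
  dur <- length(rec$samples) / rec$rate_hz
  t_in <- recording_times(rec)
  t_out <- rec$t0_s + (seq_len(floor(dur * target_hz)) - 1L) / target_hz
  out <- stats::approx(t_in, y, xout = t_out, rule = 2)$y
  raw_recording("gsr", target_hz, out, rec$t0_s)
}

#' Beat/pulse annotations
#'
#' @param event_times_s strictly increasing event times (R peaks or pulse
#'   peaks), seconds.
#' @param onset_times_s,peak_times_s,amplitudes,widths_s,peak_values pulse
#'   fields (BVP only): onset and peak times, peak-minus-onset amplitudes,
#'   per-pulse inter-onset widths (last is `NA`), absolute peak levels.
#' @return Object of class `beat_annotations`.
#' @export
beat_annotations <- function(event_times_s, onset_times_s = NULL,
                             peak_times_s = NULL, amplitudes = NULL,
                             widths_s = NULL, peak_values = NULL) {
  if (is.unsorted(event_times_s, strictly = TRUE))
    stop("event times must be strictly increasing")
  if (!is.null(amplitudes) && any(amplitudes < 0))
    stop("amplitudes must be >= 0")
  if (!is.null(onset_times_s) && !is.null(peak_times_s) &&
      length(onset_times_s) != length(peak_times_s))
    stop("onsets and peaks must have equal length")
  structure(list(event_times_s = event_times_s,
                 onset_times_s = onset_times_s,
                 peak_times_s = peak_times_s,
                 amplitudes = amplitudes, widths_s = widths_s,
                 peak_values = peak_values),
            class = "beat_annotations")
}

# Local maxima above a threshold with a refractory period; within a
# refractory conflict the larger peak wins.
find_local_peaks <- function(x, thr, refractory_n) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
                  x[2:(n - 1)] > thr) + 1L
  if (length(cand) == 0) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(0); kept <- integer(0)
  for (i in cand) {
    if (all(abs(i - kept) >= refractory_n)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Detect R peaks in an ECG recording
#'
#' Derivative-energy detector in the Pan-Tompkins tradition: the squared
#' first difference is integrated over a 150 ms moving window, candidate
#' beats are energy peaks above an adaptive (quantile-based) threshold with a
#' 250 ms refractory period, and each beat is refined to the largest absolute
#' ECG excursion within +/- 80 ms (making detection invariant to amplitude
#' scaling and polarity).
#'
#' @param rec a filtered ECG `raw_recording`.
#' @param refractory_s minimum spacing between beats, seconds.
#' @return A `beat_annotations` with `event_times_s`.
#' @export
detect_r_peaks <- function(rec, refractory_s = 0.25) {
  stopifnot(inherits(rec, "raw_recording"))
  if (rec$channel != "ecg") stop("detect_r_peaks expects an ecg recording")
  x <- rec$samples
  fs <- rec$rate_hz
  d2 <- c(0, diff(x))^2
  w <- max(3L, round(0.15 * fs))
  energy <- as.numeric(stats::filter(d2, rep(1 / w, w), sides = 2))
  energy[is.na(energy)] <- 0
  thr <- 0.10 * stats::quantile(energy, 0.99, names = FALSE)
  if (thr <= 0) stop("too-short-signal: no QRS energy found")
  refr <- max(1L, round(refractory_s * fs))
  cand <- find_local_peaks(energy, thr, refr)
  if (length(cand) < 2) stop("too-short-signal: fewer than 2 beats found")
  half <- as.integer(round(0.08 * fs))
  # resolve global polarity from the beat candidates themselves (majority
  # vote of the signal sign at energy peaks), then refine on the upright
  # signal so the dominant R lobe (not a Q/S dip) wins
  ax <- x - stats::median(x)
  pol <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    seg <- ax[lo:hi]
    if (max(seg) >= -min(seg)) 1 else -1
  }, numeric(1))
  if (stats::median(pol) < 0) ax <- -ax
  peaks <- vapply(cand, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    as.integer(lo + which.max(ax[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  # re-impose the refractory period after refinement
  if (length(peaks) > 1) {
    keep <- c(TRUE, diff(peaks) >= refr)
    while (!all(keep)) {
      peaks <- peaks[keep]
      keep <- c(TRUE, diff(peaks) >= refr)
    }
  }
  if (length(peaks) < 2) stop("too-short-signal: fewer than 2 beats found")
  beat_annotations(event_times_s = rec$t0_s + (peaks - 1L) / fs)
}

# Parabolic refinement of a maximum around index i: fit a vertex parabola at
# i and at each neighbour (the true peak may sit between samples) and take
# the best admissible estimate.
parabolic_value <- function(x, i) {
  best <- x[i]
  for (j in max(2L, i - 1L):min(length(x) - 1L, i + 1L)) {
    den <- x[j - 1] - 2 * x[j] + x[j + 1]
    if (den >= -1e-300) next  # not locally concave
    delta <- 0.5 * (x[j - 1] - x[j + 1]) / den
    if (abs(delta) > 1) next
    v <- x[j] - 0.25 * (x[j - 1] - x[j + 1]) * delta
    if (v > best) best <- v
  }
  best
}

#' Detect pulses in a BVP recording
#'
#' Pulse peaks are local maxima above an adaptive threshold with a 300 ms
#' refractory period. Each pulse onset is the trough preceding the peak
#' (searched back to the previous peak); the pulse amplitude is the
#' parabolic-refined peak level minus the onset level, and the per-pulse
#' width is the interval to the next onset.
#'
#' @param rec a BVP `raw_recording`.
#' @param refractory_s minimum peak spacing, seconds.
#' @return A `beat_annotations` with onset/peak times, amplitudes, widths and
#'   absolute peak levels; `event_times_s` are the peak times.
#' @export
detect_pulses <- function(rec, refractory_s = 0.3) {
  stopifnot(inherits(rec, "raw_recording"))
  if (rec$channel != "bvp") stop("detect_pulses expects a bvp recording")
  x <- rec$samples
  fs <- rec$rate_hz
  q <- stats::quantile(x, c(0.02, 0.98), names = FALSE)
  if (q[2] - q[1] < 1e-12) stop("too-short-signal: flat BVP signal")
  thr <- q[1] + 0.4 * (q[2] - q[1])
  peaks <- find_local_peaks(x, thr, max(1L, round(refractory_s * fs)))
  if (length(peaks) < 2) stop("too-short-signal: fewer than 2 pulses found")
  onsets <- integer(length(peaks))
  onset_val <- numeric(length(peaks))
  peak_val <- numeric(length(peaks))
  for (k in seq_along(peaks)) {
    lo <- if (k == 1) max(1L, peaks[k] - round(1.5 * fs)) else peaks[k - 1]
    win <- x[lo:peaks[k]]
    mv <- min(win)
    tol <- 1e-3 * (x[peaks[k]] - mv)
    oi <- lo + max(which(win <= mv + tol)) - 1L
    if (oi >= peaks[k]) oi <- peaks[k] - 1L
    # settle on the true trough among the few samples at/before the pick,
    # preferring the latest index on ties (flat baselines)
    jlo <- max(lo, oi - 3L)
    seg <- x[jlo:oi]
    oj <- jlo + max(which(seg == min(seg))) - 1L
    onsets[k] <- oj
    onset_val[k] <- x[oj]
    peak_val[k] <- parabolic_value(x, peaks[k])
  }
  onset_t <- rec$t0_s + (onsets - 1L) / fs
  peak_t <- rec$t0_s + (peaks - 1L) / fs
  widths <- c(diff(onset_t), NA_real_)
  beat_annotations(event_times_s = peak_t, onset_times_s = onset_t,
                   peak_times_s = peak_t,
                   amplitudes = pmax(peak_val - onset_val, 0),
                   widths_s = widths, peak_values = peak_val)
}

# Moving-average smoother with constant edge padding.
ma_smooth <- function(x, w) {
  if (w <= 1L) return(x)
  padded <- c(rep(x[1], w), x, rep(x[length(x)], w))
  sm <- as.numeric(stats::filter(padded, rep(1 / w, w), sides = 2))
  sm[(w + 1L):(w + length(x))]
}

#' Decompose a 4-Hz GSR recording into tonic and phasic components
#'
#' Deterministic filter-based decomposition: the tonic (slow conductance
#' level) is a running median (default 31 s) smoothed by a moving average
#' (default 8 s); the phasic component is the residual, so
#' `tonic + phasic == input` exactly. SCR events are scored by sparse
#' deconvolution: the lightly smoothed phasic trace is inverse-filtered by
#' the discrete Bateman kernel (time constants `tau1`, `tau2`), which turns
#' each SCR into a localised impulse cluster in the driver; clusters whose
#' calibrated amplitude reaches `min_amp` become events. The event peak is
#' the phasic maximum following the onset, giving the rise time.
#'
#' @param rec a `gsr` `raw_recording` at 4 Hz covering >= 60 s.
#' @param min_amp minimum SCR amplitude, microsiemens.
#' @param median_s,smooth_s tonic running-median and moving-average spans, s.
#' @param scr_smooth_s span of the phasic pre-detection smoother, s.
#' @param tau1,tau2 Bateman rise and decay time constants, s.
#' @return Object of class `eda_components`: `rate_hz`, `t0_s`, `tonic`,
#'   `phasic`, `scr_events` (data.frame `onset_s`, `peak_s`, `amplitude`,
#'   `rise_time_s`).
#' @export
decompose_eda <- function(rec, min_amp = 0.02, median_s = 31, smooth_s = 8,
                          scr_smooth_s = 0.5, tau1 = 0.75, tau2 = 2.0) {
  stopifnot(inherits(rec, "raw_recording"))
  if (rec$channel != "gsr") stop("decompose_eda expects a gsr recording")
  if (abs(rec$rate_hz - 4) > 1e-9) stop("decompose_eda expects a 4 Hz recording")
  x <- rec$samples
  fs <- rec$rate_hz
  if (length(x) < 60 * fs) stop("need at least 60 s of GSR signal")
  k <- round(median_s * fs); if (k %% 2 == 0) k <- k + 1L
  tonic <- as.numeric(stats::runmed(x, k, endrule = "med"))
  tonic <- ma_smooth(tonic, max(1L, round(smooth_s * fs)))
  phasic <- x - tonic
  ## SCR scoring: inverse-filter the Bateman kernel to recover the driver
  sw <- max(1L, round(scr_smooth_s * fs))
  y <- ma_smooth(phasic, sw)
  n <- length(y)
  a <- exp(-1 / (fs * tau2)); b <- exp(-1 / (fs * tau1))
  drv <- y - (a + b) * c(0, y[-n]) + a * b * c(0, 0, y[-c(n - 1, n)])
  ## calibration: driver response of one unit-amplitude smoothed kernel
  tpk <- log(tau2 / tau1) * tau1 * tau2 / (tau2 - tau1)
  pknorm <- exp(-tpk / tau2) - exp(-tpk / tau1)
  ku <- (0:round(20 * fs)) / fs
  kern <- (exp(-ku / tau2) - exp(-ku / tau1)) / pknorm
  ksm <- ma_smooth(c(rep(0, sw), kern), sw)
  m <- length(ksm)
  kd <- ksm - (a + b) * c(0, ksm[-m]) + a * b * c(0, 0, ksm[-c(m - 1, m)])
  cal <- sum(kd[kd > 0.1 * max(kd)])
  ## clusters of supra-threshold driver bins
  pk <- which(drv > 0.25 * cal * min_amp)
  ev <- NULL
  if (length(pk)) {
    grp <- cumsum(c(1, diff(pk) > 1))
    amps <- as.numeric(tapply(seq_along(pk), grp,
                              function(j) sum(drv[pk[j]]) / cal))
    ons <- as.integer(tapply(seq_along(pk), grp, function(j) pk[j][1]))
    keep <- amps >= min_amp
    amps <- amps[keep]; ons <- ons[keep]
    if (length(ons)) {
      peak_idx <- vapply(ons, function(i) {
        hi <- min(n, i + round(5 * fs))
        j <- i
        while (j < hi && y[j + 1] >= y[j]) j <- j + 1L
        as.integer(j)
      }, integer(1))
      rise <- pmax((peak_idx - ons) / fs, 1 / fs)
      ev <- data.frame(onset_s = rec$t0_s + (ons - 1L) / fs,
                       peak_s = rec$t0_s + (peak_idx - 1L) / fs,
                       amplitude = amps, rise_time_s = rise)
    }
  }
  if (is.null(ev))
    ev <- data.frame(onset_s = numeric(0), peak_s = numeric(0),
                     amplitude = numeric(0), rise_time_s = numeric(0))
  structure(list(rate_hz = fs, t0_s = rec$t0_s, tonic = tonic,
                 phasic = phasic, scr_events = ev),
            class = "eda_components")
}

#' Build the sliding-window grid for one segment
#'
#' Half-open windows `[start + k step, start + k step + window_len)` fully
#' inside the segment; a 240-s segment with the default 60 s / 1 s grid gives
#' 181 windows.
#'
#' @param segment numeric `c(start_s, end_s)`.
#' @param window_len_s window length, seconds (default 60).
#' @param step_s step, seconds (default 1).
#' @return data.frame of class `window_grid` with `start_s`, `end_s`.
#' @export
make_windows <- function(segment, window_len_s = 60, step_s = 1) {
  start <- segment[[1]]; end <- segment[[2]]
  if (end - start < window_len_s)
    stop("empty-grid: segment shorter than the window length")
  if (step_s <= 0 || window_len_s <= 0) stop("window and step must be positive")
  k <- 0:floor((end - start - window_len_s) / step_s + 1e-9)
  out <- data.frame(start_s = start + k * step_s,
                    end_s = start + k * step_s + window_len_s)
  class(out) <- c("window_grid", "data.frame")
  out
}
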