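#' Per-state physiological effect parameters
#'
#' Describes the autonomic state driving one labelled segment of a simulated
#' session: mean R-R interval and its variability, low-frequency (0.1 Hz) and
#' high-frequency (0.25 Hz) R-R modulation amplitudes, pulse-wave amplitude
#' distribution, skin-conductance-response (SCR) rate and amplitude, and the
#' tonic skin conductance level and drift.
#'
#' @param mean_rr_s mean R-R interval, seconds (0.3 < x < 2).
#' @param rr_sd_s total stationary SD of the stochastic beat-to-beat R-R
#'   variation, seconds. The noise is Gaussian but coloured like a real
#'   tachogram: a dominant narrowband respiratory component (AR(2) with
#'   poles at 0.35 Hz), a small white component and a small very slow AR(1)
#'   trend (coefficient `rr_noise_phi`). The respiratory component cancels
#'   under coarse-graining, so multiscale entropy stays estimable on 60-s
#'   windows, as it is for real recordings.
#' @param rr_noise_phi AR(1) coefficient of the slow R-R trend in `[0, 1)`.
#' @param rr_lf_amp_s amplitude of the 0.1 Hz sinusoidal R-R modulation, s.
#' @param rr_hf_amp_s amplitude of the 0.25 Hz sinusoidal R-R modulation, s.
#' @param pulse_amp_mean,pulse_amp_sd per-beat pulse-wave amplitude
#'   distribution (arbitrary units).
#' @param scr_rate_per_min Poisson rate of SCR events, events/min.
#' @param scr_amp_mean mean of the exponential SCR amplitude distribution,
#'   microsiemens.
#' @param tonic_level tonic skin conductance level, microsiemens.
#' @param tonic_drift_per_min tonic drift, microsiemens/min.
#' @return Object of class `state_effect`.
#' @export
state_effect <- function(mean_rr_s = 0.8, rr_sd_s = 0.03,
                         rr_lf_amp_s = 0.02, rr_hf_amp_s = 0.025,
                         pulse_amp_mean = 0.72, pulse_amp_sd = 0.09,
                         scr_rate_per_min = 2, scr_amp_mean = 0.4,
                         tonic_level = 5, tonic_drift_per_min = 0,
                         rr_noise_phi = 0.98) {
  if (!(mean_rr_s > 0.3 && mean_rr_s < 2))
    stop("mean_rr_s must be in (0.3, 2)")
  if (rr_noise_phi < 0 || rr_noise_phi >= 1)
    stop("rr_noise_phi must be in [0, 1)")
  nonneg <- c(rr_sd_s = rr_sd_s, rr_lf_amp_s = rr_lf_amp_s,
              rr_hf_amp_s = rr_hf_amp_s, pulse_amp_sd = pulse_amp_sd,
              scr_rate_per_min = scr_rate_per_min, scr_amp_mean = scr_amp_mean,
              pulse_amp_mean = pulse_amp_mean, tonic_level = tonic_level)
  if (any(nonneg < 0))
    stop("negative value for ", paste(names(nonneg)[nonneg < 0], collapse = ", "))
  structure(list(mean_rr_s = mean_rr_s, rr_sd_s = rr_sd_s,
                 rr_lf_amp_s = rr_lf_amp_s, rr_hf_amp_s = rr_hf_amp_s,
                 pulse_amp_mean = pulse_amp_mean, pulse_amp_sd = pulse_amp_sd,
                 scr_rate_per_min = scr_rate_per_min,
                 scr_amp_mean = scr_amp_mean, tonic_level = tonic_level,
                 tonic_drift_per_min = tonic_drift_per_min,
                 rr_noise_phi = rr_noise_phi),
            class = "state_effect")
}

#' Default per-state effects of the simulated protocol
#'
#' Encodes the expected stress physiology: the negative (stress) state raises
#' heart rate, SCR rate/amplitude and tonic level while lowering beat-to-beat
#' variability and pulse-wave amplitude; the positive state is a milder
#' arousal response; relax defaults to the neutral effect.
#'
#' @return Named list of `state_effect` objects for
#'   `relax`, `neutral`, `negative`, `positive`.
#' @export
default_state_effects <- function() {
  neutral <- state_effect(mean_rr_s = 0.80, rr_sd_s = 0.036,
                          rr_lf_amp_s = 0.008, rr_hf_amp_s = 0.010,
                          pulse_amp_mean = 0.72, pulse_amp_sd = 0.09,
                          scr_rate_per_min = 2, scr_amp_mean = 0.40,
                          tonic_level = 5.0)
  negative <- state_effect(mean_rr_s = 0.72, rr_sd_s = 0.025,
                           rr_lf_amp_s = 0.010, rr_hf_amp_s = 0.006,
                           pulse_amp_mean = 0.55, pulse_amp_sd = 0.10,
                           scr_rate_per_min = 6, scr_amp_mean = 0.90,
                           tonic_level = 6.0, tonic_drift_per_min = 0.05)
  positive <- state_effect(mean_rr_s = 0.78, rr_sd_s = 0.040,
                           rr_lf_amp_s = 0.008, rr_hf_amp_s = 0.012,
                           pulse_amp_mean = 0.70, pulse_amp_sd = 0.10,
                           scr_rate_per_min = 3, scr_amp_mean = 0.45,
                           tonic_level = 5.3)
  list(relax = neutral, neutral = neutral,
       negative = negative, positive = positive)
}

#' Session timeline of labelled segments
#'
#' The default layout follows the elicitation protocol: 3 min of relaxing
#' music before each of three 4-min picture blocks
#' (neutral, negative, positive).
#'
#' @param segments optional data.frame with columns `label`, `start_s`,
#'   `end_s`. Segments must be contiguous, non-overlapping and start at 0.
#' @return data.frame of class `session_timeline`.
#' @export
session_timeline <- function(segments = NULL) {
  if (is.null(segments)) {
    lens <- c(relax = 180, neutral = 240, relax = 180, negative = 240,
              relax = 180, positive = 240)
    ends <- cumsum(lens)
    segments <- data.frame(label = names(lens),
                           start_s = c(0, ends[-length(ends)]),
                           end_s = ends, row.names = NULL,
                           stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(segments),
            all(c("label", "start_s", "end_s") %in% names(segments)))
  if (!all(segments$label %in% c("relax", "neutral", "negative", "positive")))
    stop("segment labels must be relax/neutral/negative/positive")
  if (any(segments$end_s <= segments$start_s))
    stop("segments must have end_s > start_s")
  if (nrow(segments) > 1 &&
      any(abs(segments$start_s[-1] - segments$end_s[-nrow(segments)]) > 1e-9))
    stop("segments must be contiguous")
  if (abs(segments$start_s[1]) > 1e-9) stop("timeline must start at 0")
  class(segments) <- c("session_timeline", "data.frame")
  segments
}

#' Timeline label at given times
#' @param timeline a `session_timeline`.
#' @param t_s numeric vector of times (seconds).
#' @return integer vector of segment indices (NA outside the timeline).
#' @export
timeline_segment_at <- function(timeline, t_s) {
  idx <- findInterval(t_s, timeline$start_s)
  idx[t_s >= timeline$end_s[nrow(timeline)] | t_s < 0] <- NA_integer_
  idx
}

#' Cohort simulation configuration
#'
#' Defaults are the study conditions: 85 subjects, the default protocol
#' timeline, ECG at 400 Hz, BVP and GSR at 201 Hz.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed integer seed; the cohort is a deterministic function of the
#'   full configuration.
#' @param ecg_rate_hz,bvp_rate_hz,gsr_rate_hz sampling rates, samples/s.
#' @param effects named list with one `state_effect` per label
#'   `relax`, `neutral`, `negative`, `positive`.
#' @param timeline a `session_timeline`.
#' @param gsr_noise_sd SD of Gaussian measurement noise added to the GSR
#'   channel, microsiemens.
#' @return Object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_subjects = 85, seed = 1,
                              ecg_rate_hz = 400, bvp_rate_hz = 201,
                              gsr_rate_hz = 201,
                              effects = default_state_effects(),
                              timeline = session_timeline(),
                              gsr_noise_sd = 0.005) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (any(c(ecg_rate_hz, bvp_rate_hz, gsr_rate_hz) <= 0))
    stop("sampling rates must be positive")
  req <- c("relax", "neutral", "negative", "positive")
  if (!setequal(names(effects), req))
    stop("effects must have exactly one entry per label: ",
         paste(req, collapse = ", "))
  if (!all(vapply(effects, inherits, TRUE, "state_effect")))
    stop("all effects must be state_effect objects")
  timeline <- session_timeline(as.data.frame(timeline))
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 ecg_rate_hz = ecg_rate_hz, bvp_rate_hz = bvp_rate_hz,
                 gsr_rate_hz = gsr_rate_hz, effects = effects,
                 timeline = timeline, gsr_noise_sd = gsr_noise_sd),
            class = "cohort_sim_config")
}

# Coloured RR noise: narrowband respiratory AR(2) (poles at f_resp given
# the state's mean RR) + white + slow AR(1), with SD fractions chosen so the
# composite has stationary SD rr_sd_s and the respiratory part dominates
# (as in real tachograms, where it cancels under coarse-graining).
rr_noise_init <- function(effect, f_resp = 0.35, pole_r = 0.95) {
  sd_tot <- effect$rr_sd_s
  st <- list(sd_resp = 0.96 * sd_tot, sd_w = 0.22 * sd_tot,
             sd_s = 0.14 * sd_tot, phi = effect$rr_noise_phi)
  th <- 2 * pi * f_resp * effect$mean_rr_s
  st$a1 <- 2 * pole_r * cos(th); st$a2 <- -pole_r^2
  g0 <- (1 - st$a2) / ((1 + st$a2) * ((1 - st$a2)^2 - st$a1^2))
  st$sig_e <- st$sd_resp / sqrt(g0)
  st$z1 <- stats::rnorm(1, 0, st$sd_resp)
  st$z2 <- stats::rnorm(1, 0, st$sd_resp)
  st$s <- stats::rnorm(1, 0, st$sd_s)
  for (i in 1:20) st <- rr_noise_step(st)  # burn-in to joint stationarity
  st
}

rr_noise_step <- function(st) {
  z <- st$a1 * st$z1 + st$a2 * st$z2 + stats::rnorm(1, 0, st$sig_e)
  st$z2 <- st$z1; st$z1 <- z
  st$s <- st$phi * st$s + sqrt(1 - st$phi^2) * stats::rnorm(1, 0, st$sd_s)
  st$value <- z + st$s + stats::rnorm(1, 0, st$sd_w)
  st
}

# Re-target the noise state to a new state's parameters (keeps the running
# AR states so transitions stay continuous).
rr_noise_retarget <- function(st, effect, f_resp = 0.35, pole_r = 0.95) {
  sd_tot <- effect$rr_sd_s
  scl <- if (st$sd_resp > 0) 0.96 * sd_tot / st$sd_resp else 0
  st$z1 <- st$z1 * scl; st$z2 <- st$z2 * scl
  st$s <- st$s * (if (st$sd_s > 0) 0.14 * sd_tot / st$sd_s else 0)
  st$sd_resp <- 0.96 * sd_tot; st$sd_w <- 0.22 * sd_tot
  st$sd_s <- 0.14 * sd_tot; st$phi <- effect$rr_noise_phi
  th <- 2 * pi * f_resp * effect$mean_rr_s
  st$a1 <- 2 * pole_r * cos(th); st$a2 <- -pole_r^2
  g0 <- (1 - st$a2) / ((1 + st$a2) * ((1 - st$a2)^2 - st$a1^2))
  st$sig_e <- st$sd_resp / sqrt(g0)
  st
}

#' Simulate an R-R interval series for one state
#'
#' Beat-to-beat intervals are generated as
#' `mean_rr + lf_amp * sin(2 pi 0.1 t) + hf_amp * sin(2 pi 0.25 t) + noise`,
#' evaluated at the running beat time `t`, with coloured Gaussian noise of
#' total SD `rr_sd_s` (see [state_effect()]) and a hard floor of 0.3 s.
#' Generation continues until the cumulative sum reaches `duration_s`. Uses
#' the current RNG state.
#'
#' @param effect a `state_effect`.
#' @param duration_s positive duration to cover, seconds.
#' @return Numeric vector of R-R intervals (s) with the generating `effect`
#'   attached as attribute `"effect"`.
#' @export
simulate_rr_series <- function(effect, duration_s) {
  stopifnot(inherits(effect, "state_effect"))
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop("duration_s must be positive")
  n_max <- ceiling(duration_s / 0.3) + 10L
  rr <- numeric(n_max)
  t <- 0
  k <- 0L
  st <- rr_noise_init(effect)
  lim <- duration_s - 1e-9  # tolerate accumulated rounding
  while (t < lim) {
    st <- rr_noise_step(st)
    r <- effect$mean_rr_s +
      effect$rr_lf_amp_s * sin(2 * pi * 0.1 * t) +
      effect$rr_hf_amp_s * sin(2 * pi * 0.25 * t) + st$value
    r <- max(r, 0.3)
    k <- k + 1L
    rr[k] <- r
    t <- t + r
  }
  rr <- rr[seq_len(k)]
  attr(rr, "effect") <- effect
  rr
}

# QRS-like template sampled at rate_hz: dominant Gaussian R wave (sd 10 ms)
# with small Q/S dips.
qrs_template <- function(rate_hz, half_width_s = 0.06) {
  tt <- seq(-half_width_s, half_width_s, by = 1 / rate_hz)
  exp(-tt^2 / (2 * 0.010^2)) -
    0.25 * exp(-(tt - 0.030)^2 / (2 * 0.010^2)) -
    0.15 * exp(-(tt + 0.030)^2 / (2 * 0.010^2))
}

#' Synthesize an ECG recording from an R-R interval series
#'
#' Places one template QRS complex at each cumulative beat time. Amplitude
#' scale is arbitrary; R-peak sample positions are recoverable by peak
#' detection.
#'
#' @param rr numeric vector of R-R intervals (s), all >= 0.3.
#' @param rate_hz sampling rate (default 400).
#' @return A `raw_recording` with attribute `"beat_times_s"`.
#' @export
synthesize_ecg <- function(rr, rate_hz = 400) {
  if (length(rr) == 0) stop("rr must be non-empty")
  if (any(rr < 0.3)) stop("all RR intervals must be >= 0.3 s")
  beats <- cumsum(rr)
  dur <- sum(rr)
  n <- round(dur * rate_hz) + 1L
  x <- numeric(n)
  tpl <- qrs_template(rate_hz)
  hw <- (length(tpl) - 1L) %/% 2L
  ctr <- round(beats * rate_hz) + 1L
  for (c0 in ctr) {
    lo <- max(1L, c0 - hw); hi <- min(n, c0 + hw)
    x[lo:hi] <- x[lo:hi] + tpl[(lo - c0 + hw + 1L):(hi - c0 + hw + 1L)]
  }
  rec <- raw_recording("ecg", rate_hz, x)
  attr(rec, "beat_times_s") <- beats
  rec
}

# Single pulse shape on [0, interval): a smooth time-warped sine-squared
# lobe (fast systolic rise, slower decay) returning to exactly 0 before a
# flat zero gap ahead of the next onset. The smooth quadratic peak lets a
# parabolic-interpolating detector recover the amplitude almost exactly, and
# the flat gap makes the onset minimum exact even on a sampling grid.
pulse_shape <- function(u, interval, warp = 0.6) {
  gap <- max(0.02, 0.10 * interval)
  p <- interval - gap
  out <- numeric(length(u))
  i <- u >= 0 & u < p
  v <- (u[i] / p)^warp
  out[i] <- sin(pi * v)^2
  out
}

# Core BVP synthesis from beat times and per-beat amplitudes.
synth_bvp_core <- function(beats, amps, rate_hz, duration_s) {
  n <- round(duration_s * rate_hz) + 1L
  x <- numeric(n)
  intervals <- c(diff(beats), if (length(beats) > 1) diff(beats)[length(beats) - 1]
                 else 0.8)
  tt <- (seq_len(n) - 1L) / rate_hz
  for (k in seq_along(beats)) {
    i_lo <- ceiling(beats[k] * rate_hz) + 1L
    i_hi <- min(n, floor((beats[k] + intervals[k]) * rate_hz) + 1L)
    if (i_lo > n || i_hi < i_lo) next
    u <- tt[i_lo:i_hi] - beats[k]
    x[i_lo:i_hi] <- x[i_lo:i_hi] + amps[k] * pulse_shape(u, intervals[k])
  }
  rec <- raw_recording("bvp", rate_hz, x)
  attr(rec, "beat_times_s") <- beats
  attr(rec, "amplitudes") <- amps
  rec
}

#' Synthesize a BVP recording from an R-R interval series
#'
#' One pulse (onset at the beat time, half-cosine rise, half-cosine decay to
#' baseline) per beat; per-beat peak-minus-onset amplitudes are drawn from
#' `N(pulse_amp_mean, pulse_amp_sd)` (floored at 0.05). Uses the current RNG
#' state.
#'
#' @param rr numeric vector of R-R intervals (s), all >= 0.3.
#' @param effect a `state_effect` supplying the amplitude distribution.
#' @param rate_hz sampling rate (default 201).
#' @return A `raw_recording` with attributes `"beat_times_s"` and
#'   `"amplitudes"` (planted truth).
#' @export
synthesize_bvp <- function(rr, effect, rate_hz = 201) {
  if (length(rr) == 0) stop("rr must be non-empty")
  if (any(rr < 0.3)) stop("all RR intervals must be >= 0.3 s")
  stopifnot(inherits(effect, "state_effect"))
  beats <- c(0, cumsum(rr)[-length(rr)])
  amps <- if (effect$pulse_amp_sd > 0)
    pmax(stats::rnorm(length(beats), effect$pulse_amp_mean,
                      effect$pulse_amp_sd), 0.05)
  else rep(effect$pulse_amp_mean, length(beats))
  synth_bvp_core(beats, amps, rate_hz, sum(rr))
}

# Bateman kernel (difference of exponentials), peak-normalised to 1.
bateman_kernel <- function(t, tau1 = 0.75, tau2 = 2.0) {
  tpk <- log(tau2 / tau1) * tau1 * tau2 / (tau2 - tau1)
  peak <- exp(-tpk / tau2) - exp(-tpk / tau1)
  (exp(-t / tau2) - exp(-t / tau1)) / peak
}

# Add SCR events (onset times ev_t, amplitudes ev_a) to signal x sampled at
# rate_hz starting at time 0.
add_scr_events <- function(x, ev_t, ev_a, rate_hz, tau1 = 0.75, tau2 = 2.0,
                           kernel_len_s = 15) {
  n <- length(x)
  klen <- round(kernel_len_s * rate_hz)
  ku <- (0:klen) / rate_hz
  kern <- bateman_kernel(ku, tau1, tau2)
  for (k in seq_along(ev_t)) {
    i0 <- floor(ev_t[k] * rate_hz) + 1L
    i1 <- min(n, i0 + klen)
    if (i0 > n) next
    x[i0:i1] <- x[i0:i1] + ev_a[k] * kern[seq_len(i1 - i0 + 1L)]
  }
  x
}

#' Synthesize a GSR recording for one state
#'
#' Signal = tonic level + linear drift + a Poisson train of Bateman-shaped
#' SCR events (rate `scr_rate_per_min`, exponential amplitudes with mean
#' `scr_amp_mean`, rise/decay time constants `tau1`/`tau2`) + Gaussian
#' measurement noise. Uses the current RNG state.
#'
#' @param effect a `state_effect`.
#' @param duration_s positive duration, seconds.
#' @param rate_hz sampling rate (default 201).
#' @param noise_sd measurement noise SD, microsiemens.
#' @param tau1,tau2 Bateman rise and decay time constants, seconds.
#' @return A `raw_recording` with attribute `"scr_events"` (data.frame
#'   `onset_s`, `amplitude` — the planted truth).
#' @export
synthesize_gsr <- function(effect, duration_s, rate_hz = 201,
                           noise_sd = 0.005, tau1 = 0.75, tau2 = 2.0) {
  stopifnot(inherits(effect, "state_effect"))
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop("duration_s must be positive")
  n <- round(duration_s * rate_hz) + 1L
  tt <- (seq_len(n) - 1L) / rate_hz
  x <- effect$tonic_level + effect$tonic_drift_per_min * tt / 60
  n_ev <- stats::rpois(1, effect$scr_rate_per_min * duration_s / 60)
  ev_t <- sort(stats::runif(n_ev, 0, duration_s))
  ev_a <- stats::rexp(n_ev, rate = 1 / max(effect$scr_amp_mean, 1e-12))
  if (effect$scr_amp_mean == 0) ev_a <- rep(0, n_ev)
  x <- add_scr_events(x, ev_t, ev_a, rate_hz, tau1, tau2)
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  rec <- raw_recording("gsr", rate_hz, x)
  attr(rec, "scr_events") <- data.frame(onset_s = ev_t, amplitude = ev_a)
  rec
}

#' Simulate a cohort of three-channel sessions
#'
#' Each subject follows the configured timeline; the beat-to-beat R-R model,
#' per-beat pulse amplitudes, tonic level/drift and SCR process switch to the
#' segment's `state_effect` at each boundary. The tonic level relaxes
#' exponentially (time constant 20 s) toward each segment's target so skin
#' conductance stays continuous across boundaries. Deterministic given the
#' configuration (including its seed).
#'
#' @param config a `cohort_sim_config`.
#' @return Object of class `stress_cohort`: list with `config` and
#'   `subjects`, each subject a list of `id`, `timeline`, `recordings`
#'   (named `ecg`, `bvp`, `gsr`) and `planted` ground truth (`beats`:
#'   data.frame of beat time / R-R / segment / pulse amplitude; `scr_events`;
#'   `effects`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  tl <- config$timeline
  dur <- tl$end_s[nrow(tl)]
  subjects <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    ## --- beat process over the whole session ---
    n_max <- ceiling(dur / 0.3) + 10L
    rrs <- numeric(n_max); segs <- integer(n_max)
    t <- 0; k <- 0L
    seg_prev <- 1L
    st <- rr_noise_init(config$effects[[tl$label[1]]])
    repeat {
      seg <- timeline_segment_at(tl, t)
      ef <- config$effects[[tl$label[seg]]]
      if (seg != seg_prev) {
        st <- rr_noise_retarget(st, ef)
        seg_prev <- seg
      }
      st <- rr_noise_step(st)
      r <- ef$mean_rr_s +
        ef$rr_lf_amp_s * sin(2 * pi * 0.1 * t) +
        ef$rr_hf_amp_s * sin(2 * pi * 0.25 * t) + st$value
      r <- max(r, 0.3)
      if (t + r > dur) break
      k <- k + 1L
      rrs[k] <- r; segs[k] <- seg
      t <- t + r
    }
    rrs <- rrs[seq_len(k)]; segs <- segs[seq_len(k)]
    beat_t <- cumsum(rrs)
    ## ECG: beats at cumulative RR times, session-length record
    n_ecg <- round(dur * config$ecg_rate_hz) + 1L
    ecg_x <- numeric(n_ecg)
    tpl <- qrs_template(config$ecg_rate_hz)
    hw <- (length(tpl) - 1L) %/% 2L
    ctr <- round(beat_t * config$ecg_rate_hz) + 1L
    for (c0 in ctr) {
      lo <- max(1L, c0 - hw); hi <- min(n_ecg, c0 + hw)
      ecg_x[lo:hi] <- ecg_x[lo:hi] + tpl[(lo - c0 + hw + 1L):(hi - c0 + hw + 1L)]
    }
    ecg <- raw_recording("ecg", config$ecg_rate_hz, ecg_x)
    ## BVP: pulse onsets at beat times (beat k onset at beat_t[k-1], first at 0)
    onsets <- c(0, beat_t[-length(beat_t)])
    amp_mean <- vapply(segs, function(g) config$effects[[tl$label[g]]]$pulse_amp_mean, 0)
    amp_sd <- vapply(segs, function(g) config$effects[[tl$label[g]]]$pulse_amp_sd, 0)
    amps <- pmax(amp_mean + amp_sd * stats::rnorm(length(onsets)), 0.05)
    bvp <- synth_bvp_core(onsets, amps, config$bvp_rate_hz, dur)
    ## GSR: continuous tonic + per-segment SCR process + noise
    n_gsr <- round(dur * config$gsr_rate_hz) + 1L
    tt <- (seq_len(n_gsr) - 1L) / config$gsr_rate_hz
    tonic <- numeric(n_gsr)
    level_prev <- config$effects[[tl$label[1]]]$tonic_level
    for (g in seq_len(nrow(tl))) {
      ef <- config$effects[[tl$label[g]]]
      idx <- which(tt >= tl$start_s[g] & tt < tl$end_s[g] + 1e-9)
      u <- tt[idx] - tl$start_s[g]
      tonic[idx] <- ef$tonic_level +
        (level_prev - ef$tonic_level) * exp(-u / 20) +
        ef$tonic_drift_per_min * u / 60
      level_prev <- tonic[idx[length(idx)]]
    }
    ev_t <- numeric(0); ev_a <- numeric(0); ev_seg <- integer(0)
    for (g in seq_len(nrow(tl))) {
      ef <- config$effects[[tl$label[g]]]
      len <- tl$end_s[g] - tl$start_s[g]
      nev <- stats::rpois(1, ef$scr_rate_per_min * len / 60)
      if (nev > 0) {
        et <- sort(stats::runif(nev, tl$start_s[g], tl$end_s[g]))
        ea <- stats::rexp(nev, rate = 1 / max(ef$scr_amp_mean, 1e-12))
        ev_t <- c(ev_t, et); ev_a <- c(ev_a, ea)
        ev_seg <- c(ev_seg, rep(g, nev))
      }
    }
    gsr_x <- add_scr_events(tonic, ev_t, ev_a, config$gsr_rate_hz)
    if (config$gsr_noise_sd > 0)
      gsr_x <- gsr_x + stats::rnorm(n_gsr, 0, config$gsr_noise_sd)
    gsr <- raw_recording("gsr", config$gsr_rate_hz, gsr_x)
    subjects[[s]] <- list(
      id = s, timeline = tl,
      recordings = list(ecg = ecg, bvp = bvp, gsr = gsr),
      planted = list(
        beats = data.frame(time_s = beat_t, rr_s = rrs, segment = segs,
                           label = tl$label[segs],
                           pulse_amplitude = amps),
        scr_events = data.frame(onset_s = ev_t, amplitude = ev_a,
                                segment = ev_seg),
        effects = config$effects))
  }
  structure(list(config = config, subjects = subjects),
            class = "stress_cohort")
}

#' @export
print.stress_cohort <- function(x, ...) {
  tl <- x$config$timeline
  cat(sprintf("<stress_cohort> %d subject(s), %.0f s session, %d segments\n",
              length(x$subjects), tl$end_s[nrow(tl)], nrow(tl)))
  invisible(x)
}
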