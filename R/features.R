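# Sample SD that returns 0 for fewer than two values (used for per-event
# statistics where a lone event has zero spread by convention).
sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)

trapz_auc <- function(t, y) {
  if (length(y) < 2) return(0)
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Time-domain HRV features of one window
#'
#' @param rr R-R intervals in the window, seconds.
#' @return Named numeric vector `MEANRR` (s), `SDNN` (s, sample SD),
#'   `RMSSD` (s), `NN50` (count of successive differences strictly > 50 ms),
#'   `PNN50` (`NN50 / (n - 1)`), `HR` (60 / MEANRR, bpm). All `NA` when
#'   fewer than 3 intervals are available.
#' @export
hrv_time <- function(rr) {
  out <- c(MEANRR = NA_real_, SDNN = NA_real_, RMSSD = NA_real_,
           NN50 = NA_real_, PNN50 = NA_real_, HR = NA_real_)
  if (length(rr) < 3) return(out)
  d <- diff(rr)
  nn50 <- sum(abs(d) > 0.050)
  c(MEANRR = mean(rr), SDNN = stats::sd(rr), RMSSD = sqrt(mean(d^2)),
    NN50 = nn50, PNN50 = nn50 / (length(rr) - 1), HR = 60 / mean(rr))
}

# Welch-averaged one-sided periodogram of an interval series interpolated to
# a uniform tachogram. Returns data.frame(freq, power) with power in
# (units^2)/Hz; linear trend removed.
tachogram_psd <- function(rr, interp_hz = 4, seg_len_s = 32, overlap = 0.5) {
  t_beats <- cumsum(rr)
  span <- t_beats[length(t_beats)] - t_beats[1]
  if (span < 10) return(NULL)
  t_out <- seq(t_beats[1], t_beats[length(t_beats)], by = 1 / interp_hz)
  y <- stats::spline(t_beats, rr, xout = t_out)$y
  y <- stats::resid(stats::lm(y ~ t_out))
  n <- length(y)
  seg <- min(n, round(seg_len_s * interp_hz))
  hop <- max(1L, round(seg * (1 - overlap)))
  # end-anchored final segment so the whole series contributes
  starts <- unique(c(seq(1L, n - seg + 1L, by = hop), n - seg + 1L))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))  # Hann
  norm <- interp_hz * sum(w^2)
  acc <- numeric(seg %/% 2 + 1L)
  kk <- seq_len(seg)
  for (s0 in starts) {
    xs <- y[s0:(s0 + seg - 1L)]
    # per-segment linear detrend (Welch with detrended segments)
    fit <- stats::lm.fit(cbind(1, kk), xs)
    xw <- fit$residuals * w
    px <- abs(stats::fft(xw))^2 / norm
    acc <- acc + px[seq_len(seg %/% 2 + 1L)]
  }
  p <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when seg is even)
  p[-1] <- 2 * p[-1]
  if (seg %% 2 == 0) p[length(p)] <- p[length(p)] / 2
  data.frame(freq = (seq_along(p) - 1L) * interp_hz / seg, power = p)
}

band_power <- function(psd, lo, hi) {
  if (is.null(psd)) return(NA_real_)
  sel <- psd$freq > lo & psd$freq <= hi
  if (!any(sel)) return(0)
  df <- psd$freq[2] - psd$freq[1]
  sum(psd$power[sel]) * df
}

#' Frequency-domain HRV features of one window
#'
#' The R-R tachogram is cubic-spline interpolated to 4 Hz, linearly
#' detrended, and a Welch-averaged periodogram (32 s Hann segments, 50%
#' overlap) is integrated over the standard bands: VLF (0, 0.04], LF
#' (0.04, 0.15], HF (0.15, 0.4] Hz.
#'
#' @param rr R-R intervals in the window, seconds (>= 30 s of coverage).
#' @return Named numeric vector `VLF`, `LF`, `HF` (s^2), `LFHF` (ratio; `NA`
#'   when HF is 0).
#' @export
hrv_freq <- function(rr) {
  out <- c(VLF = NA_real_, LF = NA_real_, HF = NA_real_, LFHF = NA_real_)
  if (length(rr) < 4 || sum(rr) < 30) return(out)
  psd <- tachogram_psd(rr)
  if (is.null(psd)) return(out)
  df <- psd$freq[2] - psd$freq[1]
  if (sum(psd$power) * df < 1e-18)  # constant tachogram: no resolvable power
    return(c(VLF = 0, LF = 0, HF = 0, LFHF = NA_real_))
  vlf <- band_power(psd, 0, 0.04)
  lf <- band_power(psd, 0.04, 0.15)
  hf <- band_power(psd, 0.15, 0.40)
  c(VLF = vlf, LF = lf, HF = hf,
    LFHF = if (is.na(hf) || hf == 0) NA_real_ else lf / hf)
}

#' Sample entropy
#'
#' `SampEn(m, r)` with Chebyshev distance and self-matches excluded:
#' `-ln(A/B)` where `B` counts template pairs of length `m` within `r` and
#' `A` those of length `m + 1`, both over the first `n - m` templates. A
#' constant series returns 0 by convention; the value is `NA` when the series
#' is too short or no (m+1)-matches exist.
#'
#' @param x numeric series.
#' @param m template length (default 2).
#' @param r_factor tolerance as a multiple of the sample SD of `x`.
#' @param r absolute tolerance; overrides `r_factor` when given.
#' @return Scalar sample entropy (dimensionless).
#' @export
sample_entropy <- function(x, m = 2, r_factor = 0.2, r = NULL) {
  n <- length(x)
  if (n < m + 2) return(NA_real_)
  s <- stats::sd(x)
  if (s == 0) return(0)
  if (is.null(r)) r <- r_factor * s
  nt <- n - m
  # pairwise Chebyshev distances over m-length and (m+1)-length templates,
  # both indexed 1..nt so every m-template can extend
  dmax <- matrix(0, nt, nt)
  for (k in 0:(m - 1)) {
    dk <- abs(outer(x[(1 + k):(nt + k)], x[(1 + k):(nt + k)], "-"))
    dmax <- pmax(dmax, dk)
  }
  b_mat <- dmax <= r
  dk <- abs(outer(x[(1 + m):(nt + m)], x[(1 + m):(nt + m)], "-"))
  a_mat <- b_mat & (pmax(dmax, dk) <= r)
  B <- (sum(b_mat) - nt) / 2
  A <- (sum(a_mat) - nt) / 2
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

#' Multiscale sample entropy
#'
#' Coarse-grains the series by non-overlapping means of `tau` consecutive
#' values and applies [sample_entropy()] at each scale, with the tolerance
#' `r` fixed from the scale-1 series.
#'
#' @param x numeric series (R-R intervals in a window).
#' @param scales integer scales (default 1:5).
#' @param m template length.
#' @param r_factor tolerance factor applied to the scale-1 sample SD.
#' @return Named numeric vector `MSE<scale>`.
#' @export
multiscale_entropy <- function(x, scales = 1:5, m = 2, r_factor = 0.2) {
  s1 <- stats::sd(x)
  if (is.na(s1)) s1 <- 0
  r <- r_factor * s1
  out <- vapply(scales, function(tau) {
    ncg <- floor(length(x) / tau)
    if (ncg < m + 2) return(NA_real_)
    cg <- colMeans(matrix(x[seq_len(ncg * tau)], nrow = tau))
    if (s1 == 0) return(0)
    sample_entropy(cg, m = m, r = r)
  }, numeric(1))
  names(out) <- paste0("MSE", scales)
  out
}

#' BVP features of one window
#'
#' Pulse-rate-variability statistics of the pulse-peak interval series
#' (computed with the same estimators as the ECG analogues; the LF band for
#' BVP is 0-0.15 Hz) plus pulse-wave amplitude summaries.
#'
#' @param beats a `beat_annotations` from [detect_pulses()].
#' @param window numeric `c(start_s, end_s)`.
#' @return Named numeric vector of the 12 BVP registry features (without the
#'   `_BVP` suffix).
#' @export
bvp_features <- function(beats, window) {
  out <- stats::setNames(rep(NA_real_, 12),
                         c("PR", "SDNN", "RMSSD", "MEANRR", "LF", "HF",
                           "WIDTH", "H_W", "MAXPA", "STDPA", "MEANPA", "HIGH"))
  pk_in <- which(beats$peak_times_s >= window[1] & beats$peak_times_s < window[2])
  if (length(pk_in) < 4) return(out)
  pi_s <- diff(beats$peak_times_s[pk_in])
  ht <- hrv_time(pi_s)
  psd <- if (sum(pi_s) >= 30) tachogram_psd(pi_s) else NULL
  lf <- band_power(psd, 0, 0.15)
  hf <- band_power(psd, 0.15, 0.40)
  amps <- beats$amplitudes[pk_in]
  wids <- beats$widths_s[pk_in]
  ok <- !is.na(wids) & wids > 0
  out["PR"] <- 60 / mean(pi_s)
  out["SDNN"] <- ht["SDNN"]; out["RMSSD"] <- ht["RMSSD"]
  out["MEANRR"] <- ht["MEANRR"]
  out["LF"] <- lf; out["HF"] <- hf
  out["WIDTH"] <- if (any(ok)) mean(wids[ok]) else NA_real_
  out["H_W"] <- if (any(ok)) mean(amps[ok] / wids[ok]) else NA_real_
  out["MAXPA"] <- max(amps); out["STDPA"] <- sd0(amps)
  out["MEANPA"] <- mean(amps); out["HIGH"] <- mean(beats$peak_values[pk_in])
  out
}

#' GSR features of one window
#'
#' Tonic statistics (mean, SD, trapezoidal area), phasic statistics (SD,
#' area), SCR event statistics (count, amplitude and rise-time summaries;
#' all 0 when no event onset falls in the window) and the total spectral
#' power of the mean-removed 4-Hz signal.
#'
#' @param eda an `eda_components` (possibly standardised).
#' @param window numeric `c(start_s, end_s)`.
#' @return Named numeric vector of the 12 GSR registry features (without the
#'   `_GSR` suffix).
#' @export
gsr_features <- function(eda, window) {
  tt <- eda$t0_s + (seq_along(eda$tonic) - 1L) / eda$rate_hz
  sel <- tt >= window[1] & tt < window[2]
  out <- stats::setNames(rep(NA_real_, 12),
                         c("MEANT", "STDT", "AUCT", "STDR", "AUCR", "NUMP",
                           "MAXPA", "MEANPA", "STDPA", "MEANPR", "STDPR", "PSD"))
  if (sum(sel) < 2) return(out)
  ton <- eda$tonic[sel]; pha <- eda$phasic[sel]; tsub <- tt[sel]
  out["MEANT"] <- mean(ton); out["STDT"] <- stats::sd(ton)
  out["AUCT"] <- trapz_auc(tsub, ton)
  out["STDR"] <- stats::sd(pha); out["AUCR"] <- trapz_auc(tsub, pha)
  ev <- eda$scr_events
  ine <- ev$onset_s >= window[1] & ev$onset_s < window[2]
  out["NUMP"] <- sum(ine)
  if (any(ine)) {
    a <- ev$amplitude[ine]; rt <- ev$rise_time_s[ine]
    out["MAXPA"] <- max(a); out["MEANPA"] <- mean(a); out["STDPA"] <- sd0(a)
    out["MEANPR"] <- mean(rt); out["STDPR"] <- sd0(rt)
  } else {
    out[c("MAXPA", "MEANPA", "STDPA", "MEANPR", "STDPR")] <- 0
  }
  x <- ton + pha
  out["PSD"] <- mean((x - mean(x))^2)  # total power of the windowed signal
  out
}

# Standardise EDA components per subject (session-level z-scores); event
# amplitudes are rescaled by the phasic SD so they stay commensurate.
standardize_eda <- function(eda) {
  ms <- mean(eda$tonic); ss <- stats::sd(eda$tonic)
  mp <- mean(eda$phasic); sp <- stats::sd(eda$phasic)
  if (ss == 0) ss <- 1
  if (sp == 0) sp <- 1
  eda$tonic <- (eda$tonic - ms) / ss
  eda$phasic <- (eda$phasic - mp) / sp
  eda$scr_events$amplitude <- eda$scr_events$amplitude / sp
  eda
}

#' Extract the 39-feature sliding-window matrix from a cohort
#'
#' Runs the full preprocessing chain per subject (band-pass + notch for ECG
#' and BVP, 4-Hz resampling + tonic/phasic decomposition for GSR), builds the
#' 60 s / 1 s window grid inside every segment long enough to hold a window,
#' and computes the 39 registry features per window. Missing values are
#' imputed by the per-subject-per-segment median (a message reports the
#' count); a column more than 20% missing aborts with a diagnostic.
#'
#' @param cohort a `stress_cohort` (or a single subject entry of one).
#' @param window_len_s,step_s window grid parameters (defaults 60 and 1 s).
#' @param filter apply the conditioning filters before event detection
#'   (disable for noise-free synthetic recovery studies).
#' @param gsr_normalize standardise tonic/phasic per subject before GSR
#'   feature computation (Table-style negative tonic means; raw microsiemens
#'   when `FALSE`).
#' @param notch_hz powerline notch frequency (Hz).
#' @param max_missing maximum tolerated missing fraction per feature column
#'   before aborting (default 0.2). Raise for deliberately degenerate
#'   studies (e.g. noise-free recovery runs where spectral ratios are
#'   undefined by construction).
#' @return data.frame of class `feature_matrix`: columns `subject`,
#'   `segment`, `label`, `window`, `window_start_s`, then the 39 features.
#' @export
extract_feature_matrix <- function(cohort, window_len_s = 60, step_s = 1,
                                   filter = TRUE, gsr_normalize = TRUE,
                                   notch_hz = 50, max_missing = 0.2) {
  stopifnot(inherits(cohort, "stress_cohort"))
  reg <- feature_registry()
  vals_list <- list()
  meta_list <- list()
  for (subj in cohort$subjects) {
    tl <- subj$timeline
    ecg <- subj$recordings$ecg
    bvp <- subj$recordings$bvp
    if (filter) {
      ecg <- notch_filter(bandpass_filter(ecg), f0_hz = notch_hz)
      bvp <- notch_filter(bandpass_filter(bvp), f0_hz = notch_hz)
    }
    r_ann <- detect_r_peaks(ecg)
    p_ann <- detect_pulses(bvp)
    g4 <- resample_gsr(subj$recordings$gsr, 4)
    eda <- decompose_eda(g4)
    if (gsr_normalize) eda <- standardize_eda(eda)
    beat_t <- r_ann$event_times_s
    for (g in seq_len(nrow(tl))) {
      if (tl$end_s[g] - tl$start_s[g] < window_len_s) next
      wg <- make_windows(c(tl$start_s[g], tl$end_s[g]), window_len_s, step_s)
      for (w in seq_len(nrow(wg))) {
        win <- c(wg$start_s[w], wg$end_s[w])
        bt <- beat_t[beat_t >= win[1] & beat_t < win[2]]
        rr <- diff(bt)
        ht <- hrv_time(rr)
        hf <- hrv_freq(rr)
        mse <- multiscale_entropy(rr)
        bf <- bvp_features(p_ann, win)
        gf <- gsr_features(eda, win)
        vals <- c(ht[c("MEANRR", "SDNN", "RMSSD", "NN50", "PNN50", "HR")],
                  hf[c("VLF", "LF", "HF", "LFHF")], mse, bf, gf)
        i <- length(vals_list) + 1L
        vals_list[[i]] <- unname(vals)
        meta_list[[i]] <- list(subj$id, g, tl$label[g], w, win[1])
      }
    }
  }
  vm <- do.call(rbind, vals_list)
  colnames(vm) <- reg$all
  fm <- data.frame(
    subject = vapply(meta_list, function(m) as.numeric(m[[1]]), 0),
    segment = vapply(meta_list, function(m) as.numeric(m[[2]]), 0),
    label = vapply(meta_list, function(m) as.character(m[[3]]), ""),
    window = vapply(meta_list, function(m) as.numeric(m[[4]]), 0),
    window_start_s = vapply(meta_list, function(m) as.numeric(m[[5]]), 0),
    stringsAsFactors = FALSE)
  fm <- cbind(fm, as.data.frame(vm))
  rownames(fm) <- NULL
  ## imputation: per-subject-per-segment median
  n_imputed <- 0L
  for (col in reg$all) {
    miss_frac <- mean(is.na(fm[[col]]))
    if (miss_frac > max_missing)
      stop(sprintf("feature %s is %.0f%% missing (> %.0f%%); check inputs",
                   col, 100 * miss_frac, 100 * max_missing))
    if (miss_frac > 0) {
      for (key in unique(paste(fm$subject, fm$segment))) {
        idx <- paste(fm$subject, fm$segment) == key
        v <- fm[[col]][idx]
        if (anyNA(v)) {
          med <- stats::median(v, na.rm = TRUE)
          if (is.finite(med)) {
            n_imputed <- n_imputed + sum(is.na(v))
            v[is.na(v)] <- med
            fm[[col]][idx] <- v
          }
        }
      }
    }
  }
  if (n_imputed > 0)
    message(sprintf("imputed %d missing feature value(s) by segment median",
                    n_imputed))
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d windows x %d features (%d subject(s), %d segment(s))\n",
    nrow(x), length(feature_registry()$all),
    length(unique(x$subject)), length(unique(paste(x$subject, x$segment)))))
  invisible(x)
}
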