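# Independent oracles and small builders shared across test files.

# Naive O(n^2) sample-entropy oracle: explicit template loops, Chebyshev
# distance, self-matches excluded, both template lengths over i = 1..n-m.
brute_sampen <- function(x, m = 2, r) {
  n <- length(x)
  nt <- n - m
  B <- 0L; A <- 0L
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      db <- 0
      for (k in 0:(m - 1)) db <- max(db, abs(x[i + k] - x[j + k]))
      if (db <= r) {
        B <- B + 1L
        if (max(db, abs(x[i + m] - x[j + m])) <= r) A <- A + 1L
      }
    }
  }
  if (B == 0L || A == 0L) return(NA_real_)
  -log(A / B)
}

# Brute-force sliding-window count: enumerate placements directly.
brute_window_count <- function(len, win, step) {
  k <- 0L; s <- 0
  while (s + win <= len + 1e-9) { k <- k + 1L; s <- s + step }
  k
}

# Short six-segment protocol timeline (relax/neutral/relax/negative/relax/
# positive) with segments of seg_len seconds, for fast end-to-end runs.
short_timeline <- function(seg_len = 70) {
  labels <- c("relax", "neutral", "relax", "negative", "relax", "positive")
  ends <- cumsum(rep(seg_len, 6))
  session_timeline(data.frame(label = labels, start_s = ends - seg_len,
                              end_s = ends))
}

# Noise-free state effects (no RR noise or modulation, fixed pulse
# amplitude, no GSR drift) with grid-aligned mean RR per state.
noise_free_effects <- function(scr_rate = 0) {
  mk <- function(mean_rr, pa, tonic)
    state_effect(mean_rr_s = mean_rr, rr_sd_s = 0, rr_lf_amp_s = 0,
                 rr_hf_amp_s = 0, pulse_amp_mean = pa, pulse_amp_sd = 0,
                 scr_rate_per_min = scr_rate, scr_amp_mean = 0.5,
                 tonic_level = tonic, tonic_drift_per_min = 0)
  list(relax = mk(0.80, 0.72, 5), neutral = mk(0.80, 0.72, 5),
       negative = mk(0.72, 0.55, 6), positive = mk(0.76, 0.70, 5.3))
}

# Window-level feature table with a transition-adjacent effect that fades
# within each emotion segment (exponential decay over windows), on top of a
# large per-subject baseline: the construction where paired transition
# analysis should beat unpaired state comparison.
fading_fm <- function(n_subjects, bump = c(negative = 1, positive = 0.8),
                      tau = 3, W = 10, between_sd = 1.5, within_sd = 0.5) {
  labels <- c("relax", "neutral", "relax", "negative", "relax", "positive")
  ns <- length(labels)
  subj <- rep(seq_len(n_subjects), each = ns * W)
  segment <- rep(rep(seq_len(ns), each = W), times = n_subjects)
  label <- labels[segment]
  window <- rep(seq_len(W), times = n_subjects * ns)
  offs <- stats::rnorm(n_subjects, 0, between_sd)
  bmp <- ifelse(label %in% names(bump), bump[label], 0) * exp(-(window - 1) / tau)
  x <- offs[subj] + bmp + stats::rnorm(length(subj), 0, within_sd)
  as_feature_matrix(data.frame(subject = subj, segment = segment,
                               label = label, window = window,
                               X = as.numeric(x)))
}

# Multi-feature noise table in protocol layout with registry-style naming,
# for classification and compare_methods smoke tests.
noise_fm <- function(n_subjects = 30, W = 4, features = paste0("F", 1:4),
                     label_shift = NULL) {
  labels <- c("neutral", "negative", "positive")
  subj <- rep(seq_len(n_subjects), each = 3 * W)
  segment <- rep(rep(1:3, each = W), n_subjects)
  label <- labels[segment]
  df <- data.frame(subject = subj, segment = segment, label = label,
                   window = rep(seq_len(W), n_subjects * 3),
                   stringsAsFactors = FALSE)
  for (f in features) df[[f]] <- stats::rnorm(nrow(df))
  if (!is.null(label_shift))
    df[[features[1]]] <- df[[features[1]]] * 0.05 +
      label_shift * as.numeric(factor(label))
  as_feature_matrix(df)
}
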