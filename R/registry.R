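#' The canonical 39-feature registry
#'
#' The pipeline computes 15 ECG, 12 BVP and 12 GSR features per sliding
#' window. The order returned here is canonical: it fixes the column order of
#' every feature matrix and is the tie-break order of the greedy redundancy
#' filter (earlier features are kept in preference to later ones).
#'
#' ECG features are heart-rate-variability summaries of the R-R interval
#' series (time domain, Welch band powers, multiscale sample entropy at
#' scales 1-5). BVP features summarise the pulse-peak interval series
#' (pulse-rate variability) and per-pulse amplitudes. GSR features summarise
#' the tonic and phasic components of skin conductance and the detected
#' skin-conductance responses (SCRs).
#'
#' Note `PR_BVP` is the pulse rate in beats/min (the rate analogue of
#' `HR_ECG`), and `HIGH_BVP` is the mean absolute signal level at pulse
#' peaks, distinct from `MEANPA_BVP` (mean peak-minus-onset amplitude).
#' `AUCR_GSR` is also known as AUCP (area under the phasic curve).
#'
#' @return Named list with elements `ecg`, `bvp`, `gsr` (character vectors of
#'   feature names) and `all` (the 39 names in canonical order).
#' @export
#' @examples
#' length(feature_registry()$all) # 39
feature_registry <- function() {
  ecg <- c("MEANRR_ECG", "SDNN_ECG", "RMSSD_ECG", "NN50_ECG", "PNN50_ECG",
           "HR_ECG", "VLF_ECG", "LF_ECG", "HF_ECG", "LFHF_ECG",
           paste0("MSE", 1:5, "_ECG"))
  bvp <- c("PR_BVP", "SDNN_BVP", "RMSSD_BVP", "MEANRR_BVP", "LF_BVP",
           "HF_BVP", "WIDTH_BVP", "H_W_BVP", "MAXPA_BVP", "STDPA_BVP",
           "MEANPA_BVP", "HIGH_BVP")
  gsr <- c("MEANT_GSR", "STDT_GSR", "AUCT_GSR", "STDR_GSR", "AUCR_GSR",
           "NUMP_GSR", "MAXPA_GSR", "MEANPA_GSR", "STDPA_GSR", "MEANPR_GSR",
           "STDPR_GSR", "PSD_GSR")
  stopifnot(length(ecg) == 15L, length(bvp) == 12L, length(gsr) == 12L)
  list(ecg = ecg, bvp = bvp, gsr = gsr, all = c(ecg, bvp, gsr))
}

#' Signal group of each feature
#'
#' @param features character vector of registry feature names.
#' @return character vector in `{"ECG","BVP","GSR"}`.
#' @export
feature_signal_group <- function(features) {
  reg <- feature_registry()
  out <- rep(NA_character_, length(features))
  out[features %in% reg$ecg] <- "ECG"
  out[features %in% reg$bvp] <- "BVP"
  out[features %in% reg$gsr] <- "GSR"
  if (anyNA(out)) {
    stop("unknown feature name(s): ",
         paste(features[is.na(out)], collapse = ", "))
  }
  out
}

#' Construct a raw recording
#'
#' A single channel's uniformly sampled amplitude series.
#'
#' @param channel one of `"ecg"`, `"bvp"`, `"gsr"`.
#' @param rate_hz sampling rate in samples/s (> 0).
#' @param samples numeric vector of finite amplitudes.
#' @param t0_s start offset in seconds.
#' @return Object of class `raw_recording`.
#' @export
raw_recording <- function(channel, rate_hz, samples, t0_s = 0) {
  channel <- match.arg(channel, c("ecg", "bvp", "gsr"))
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("rate_hz must be a positive scalar")
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("samples must be finite")
  structure(list(channel = channel, rate_hz = rate_hz,
                 samples = samples, t0_s = t0_s),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> channel=%s rate=%g Hz n=%d (%.1f s, t0=%g s)\n",
              x$channel, x$rate_hz, length(x$samples),
              length(x$samples) / x$rate_hz, x$t0_s))
  invisible(x)
}

#' Sample times of a recording
#' @param rec a `raw_recording`.
#' @return numeric vector of times in seconds (first sample at `t0_s`).
#' @export
recording_times <- function(rec) {
  rec$t0_s + (seq_along(rec$samples) - 1L) / rec$rate_hz
}

#' Duration of a recording in seconds
#' @param rec a `raw_recording`.
#' @export
recording_duration <- function(rec) length(rec$samples) / rec$rate_hz
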