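#' Validate and tag a window-level feature table
#'
#' Checks the feature-matrix contract (index columns `subject`, `segment`,
#' `label`, `window` plus numeric feature columns) and attaches the
#' `feature_matrix` class, so selection and evaluation functions accept
#' externally built tables.
#'
#' @param df a data.frame.
#' @return `df` with class `feature_matrix`.
#' @export
as_feature_matrix <- function(df) {
  need <- c("subject", "segment", "label", "window")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing index column(s): ", paste(miss, collapse = ", "))
  if (!all(df$label %in% c("relax", "neutral", "negative", "positive")))
    stop("labels must be relax/neutral/negative/positive")
  class(df) <- unique(c("feature_matrix", class(df)))
  df
}

#' Synthetic window-level feature matrix with planted state effects
#'
#' Direct generator of a window-level feature table following the protocol
#' layout (relax, neutral, relax, negative, relax, positive), bypassing
#' signal synthesis. Each value is
#' `label_mean + subject_offset + window_noise`; subject offsets are
#' `N(0, between_sd)` and shared across segments, so paired (within-subject)
#' analyses cancel them while unpaired analyses must overcome them. Used for
#' power and type-I studies of the selection methods. Uses the current RNG
#' state.
#'
#' @param n_subjects number of subjects.
#' @param label_means named numeric vector of per-state means for labels
#'   `relax`, `neutral`, `negative`, `positive`.
#' @param between_sd SD of the per-subject random offset.
#' @param within_sd SD of the per-window noise.
#' @param windows_per_segment windows simulated per segment.
#' @param feature_name name of the single feature column.
#' @return A `feature_matrix` with one feature column.
#' @export
synthetic_feature_matrix <- function(n_subjects = 85,
                                     label_means = c(relax = 0, neutral = 0,
                                                     negative = 0, positive = 0),
                                     between_sd = 1, within_sd = 1,
                                     windows_per_segment = 2,
                                     feature_name = "X") {
  labels <- c("relax", "neutral", "relax", "negative", "relax", "positive")
  ns <- length(labels)
  w <- windows_per_segment
  n <- n_subjects * ns * w
  subj <- rep(seq_len(n_subjects), each = ns * w)
  segment <- rep(rep(seq_len(ns), each = w), times = n_subjects)
  label <- labels[segment]
  window <- rep(seq_len(w), times = n_subjects * ns)
  offs <- stats::rnorm(n_subjects, 0, between_sd)
  x <- label_means[label] + offs[subj] + stats::rnorm(n, 0, within_sd)
  df <- data.frame(subject = subj, segment = segment, label = label,
                   window = window, stringsAsFactors = FALSE)
  df[[feature_name]] <- as.numeric(x)
  as_feature_matrix(df)
}
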