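#' Write a cohort to delimited text
#'
#' One CSV per subject and channel (`subject<ID>_<channel>.csv` with columns
#' `time_s,value`) plus a JSON sidecar per subject
#' (`subject<ID>_meta.json`) holding the timeline and the planted ground
#' truth.
#'
#' @param cohort a `stress_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "stress_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (subj in cohort$subjects) {
    for (ch in names(subj$recordings)) {
      rec <- subj$recordings[[ch]]
      f <- file.path(dir, sprintf("subject%03d_%s.csv", subj$id, ch))
      utils::write.csv(data.frame(time_s = recording_times(rec),
                                  value = rec$samples),
                       f, row.names = FALSE)
      written <- c(written, f)
    }
    meta <- list(
      id = subj$id,
      rates_hz = lapply(subj$recordings, function(r) r$rate_hz),
      timeline = as.data.frame(subj$timeline),
      planted = list(beats = subj$planted$beats,
                     scr_events = subj$planted$scr_events))
    f <- file.path(dir, sprintf("subject%03d_meta.json", subj$id))
    jsonlite::write_json(meta, f, auto_unbox = TRUE, digits = NA)
    written <- c(written, f)
  }
  invisible(written)
}

#' Read one subject's recordings back from delimited text
#'
#' Round-trips the output of [write_cohort_csv()].
#'
#' @param dir directory written by [write_cohort_csv()].
#' @param id subject id.
#' @return List with `recordings` (named `raw_recording`s), `timeline` and
#'   `planted`.
#' @export
read_subject_csv <- function(dir, id) {
  meta <- jsonlite::read_json(
    file.path(dir, sprintf("subject%03d_meta.json", id)), simplifyVector = TRUE)
  recs <- list()
  for (ch in c("ecg", "bvp", "gsr")) {
    f <- file.path(dir, sprintf("subject%03d_%s.csv", id, ch))
    d <- utils::read.csv(f)
    recs[[ch]] <- raw_recording(ch, meta$rates_hz[[ch]], d$value,
                                t0_s = d$time_s[1])
  }
  list(id = id, recordings = recs,
       timeline = session_timeline(as.data.frame(meta$timeline)),
       planted = meta$planted)
}

#' Write / read a feature matrix as CSV
#'
#' @param fm a `feature_matrix`.
#' @param path CSV path.
#' @export
write_feature_matrix <- function(fm, path) {
  utils::write.csv(as.data.frame(fm), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  fm <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(feature_registry()$all, names(fm))
  if (length(missing))
    stop("feature matrix misses column(s): ", paste(missing, collapse = ", "))
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

#' Serialise a selection result to JSON
#'
#' @param sel a `selection_result`.
#' @param path output path.
#' @export
write_selection_json <- function(sel, path) {
  jsonlite::write_json(
    list(method = sel$method, alpha = sel$alpha,
         final_subset = sel$final_subset, table = sel$table),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
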