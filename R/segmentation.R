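#' Segment labelling rule
#'
#' Fixed 1-s sliding windows with 50% overlap. A window is labelled
#' `artifact` when any annotated interval intersects it by at least
#' `min_intersection_s` (0.1 s) -- or by any amount when the interval itself
#' is no longer than 0.1 s; `nonartifact` when no interval intersects it at
#' all; and `ignored` otherwise (an intersection shorter than 0.1 s with an
#' interval longer than 0.1 s). Ignored windows are excluded from training
#' and evaluation but retained in an audit table.
#'
#' @param window_s window length, seconds.
#' @param overlap fractional overlap between consecutive windows.
#' @param min_intersection_s intersection threshold, seconds.
#' @return A `label_rule` object.
#' @export
label_rule <- function(window_s = 1.0, overlap = 0.5, min_intersection_s = 0.1) {
  stop_if_not(overlap > 0 && overlap < 1, "overlap must be in (0, 1)")
  stop_if_not(min_intersection_s > 0 && min_intersection_s < window_s,
              "min_intersection_s must be in (0, window_s)")
  structure(list(window_s = window_s, overlap = overlap,
                 min_intersection_s = min_intersection_s,
                 step_s = window_s * (1 - overlap)),
            class = "label_rule")
}

#' Window onsets of a recording
#'
#' Onsets 0, 0.5, 1.0, ... such that every window fits entirely within the
#' recording; a trailing partial window is never emitted. For duration `d`
#' (seconds) the count is `floor((d - window_s) / step) + 1`.
#'
#' @param duration_s recording duration, seconds.
#' @param rule a [label_rule()].
#' @return Numeric vector of onsets (empty when the recording is shorter than
#'   one window).
#' @export
window_onsets <- function(duration_s, rule = label_rule()) {
  if (duration_s < rule$window_s) return(numeric(0))
  n <- floor((duration_s - rule$window_s) / rule$step_s + 1e-9) + 1
  (seq_len(n) - 1) * rule$step_s
}

#' Label a single window against annotated intervals
#'
#' Intersections are computed in continuous seconds on half-open intervals
#' `[onset, onset + duration)`; the artifact test is per interval (any
#' qualifying interval suffices), not summed overlap.
#'
#' @param onset_s window onset, seconds.
#' @param intervals annotation data frame (`onset_s`, `duration_s`, `label`).
#' @param rule a [label_rule()].
#' @return `"artifact"`, `"nonartifact"` or `"ignored"`.
#' @export
assign_label <- function(onset_s, intervals, rule = label_rule()) {
  if (is.null(intervals) || nrow(intervals) == 0) return("nonartifact")
  ws <- onset_s
  we <- onset_s + rule$window_s
  inter <- pmax(0, pmin(we, intervals$onset_s + intervals$duration_s) -
                   pmax(ws, intervals$onset_s))
  eps <- 1e-9
  if (all(inter <= eps)) return("nonartifact")
  qualifying <- inter >= rule$min_intersection_s - eps |
    (intervals$duration_s <= rule$min_intersection_s + eps & inter > eps)
  if (any(qualifying)) "artifact" else "ignored"
}

#' Segment one recording into labelled windows
#'
#' @param rec an [recording()].
#' @param rule a [label_rule()].
#' @return Data frame with `segment_id`, `recording_id`, `subject_id`,
#'   `onset_s`, `label` (including `ignored` rows), one per window.
#' @export
segment_recording <- function(rec, rule = label_rule()) {
  onsets <- window_onsets(recording_duration(rec), rule)
  labels <- vapply(onsets, assign_label, character(1),
                   intervals = rec$annotations, rule = rule)
  data.frame(segment_id = sprintf("%s@%06.1f", rec$recording_id, onsets),
             recording_id = rec$recording_id,
             subject_id = rec$subject_id,
             onset_s = onsets,
             label = labels,
             stringsAsFactors = FALSE)
}

#' Segment a set of recordings into the modelling dataset
#'
#' @param recordings list of [recording()] objects.
#' @param rule a [label_rule()].
#' @return A `segment_dataset`: list with `segments` (artifact/nonartifact
#'   windows), `ignored` (the audit table of ignored windows) and `counts`
#'   (per-class tally over all windows).
#' @export
segment_dataset <- function(recordings, rule = label_rule()) {
  all <- do.call(rbind, lapply(recordings, segment_recording, rule = rule))
  counts <- c(artifact = sum(all$label == "artifact"),
              nonartifact = sum(all$label == "nonartifact"),
              ignored = sum(all$label == "ignored"))
  out <- list(segments = all[all$label != "ignored", , drop = FALSE],
              ignored = all[all$label == "ignored", , drop = FALSE],
              counts = counts)
  rownames(out$segments) <- NULL
  rownames(out$ignored) <- NULL
  structure(out, class = "segment_dataset")
}

#' @export
print.segment_dataset <- function(x, ...) {
  cat(sprintf("<segment_dataset> %d artifact / %d nonartifact / %d ignored windows\n",
              x$counts["artifact"], x$counts["nonartifact"], x$counts["ignored"]))
  invisible(x)
}

#' Extract the raw signal slice of one segment
#' @param rec the source [recording()].
#' @param onset_s window onset, seconds.
#' @param window_s window length, seconds.
#' @return channels x (sr * window_s) matrix.
#' @export
segment_signal <- function(rec, onset_s, window_s = 1.0) {
  i0 <- floor(onset_s * rec$sr) + 1
  idx <- i0:(i0 + round(window_s * rec$sr) - 1)
  stop_if_not(max(idx) <= ncol(rec$signal), "segment extends past recording end")
  rec$signal[, idx, drop = FALSE]
}
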