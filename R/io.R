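#' Construct an EEG recording object
#'
#' The raw unit of the pipeline: a continuous multichannel signal with its
#' sampling rate, channel names and (optionally) expert-annotated artifact
#' intervals.
#'
#' @param signal numeric matrix, channels x samples, in volts.
#' @param sr sampling rate in Hz.
#' @param channel_names character vector, one name per signal row.
#' @param subject_id,recording_id identifiers; a subject may have several
#'   recordings and cross-validation folds are always split by subject.
#' @param annotations data frame with columns `onset_s`, `duration_s`,
#'   `label` (seconds from recording start, half-open intervals
#'   `[onset, onset + duration)`), or `NULL`.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(signal, sr, channel_names,
                      subject_id = "sub01", recording_id = "rec01",
                      annotations = NULL) {
  stop_if_not(is.matrix(signal) && is.numeric(signal),
              "`signal` must be a numeric channels x samples matrix")
  stop_if_not(all(is.finite(signal)), "`signal` must contain only finite values")
  stop_if_not(is.numeric(sr) && length(sr) == 1 && sr > 0, "`sr` must be > 0")
  stop_if_not(length(channel_names) == nrow(signal),
              "`channel_names` length must equal the number of signal rows")
  if (is.null(annotations)) {
    annotations <- empty_annotations()
  }
  rec <- structure(
    list(subject_id = as.character(subject_id),
         recording_id = as.character(recording_id),
         sr = as.numeric(sr),
         channel_names = as.character(channel_names),
         signal = signal,
         annotations = annotations),
    class = "eeg_recording")
  rec$annotations <- validate_annotations(annotations,
                                          duration_s = recording_duration(rec))
  rec
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s/%s: %d channels x %d samples @ %g Hz (%.1f s), %d annotation(s)\n",
              x$subject_id, x$recording_id, nrow(x$signal), ncol(x$signal),
              x$sr, recording_duration(x), nrow(x$annotations)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`.
#' @return Duration in seconds (`samples / sr`).
#' @export
recording_duration <- function(rec) ncol(rec$signal) / rec$sr

empty_annotations <- function() {
  data.frame(onset_s = numeric(0), duration_s = numeric(0),
             label = character(0), stringsAsFactors = FALSE)
}

# Validate an annotation table; returns it sorted by onset.
validate_annotations <- function(ann, duration_s = NULL) {
  stop_if_not(is.data.frame(ann) &&
                all(c("onset_s", "duration_s", "label") %in% names(ann)),
              "annotations need columns onset_s, duration_s, label")
  if (nrow(ann) == 0) return(empty_annotations())
  bad <- which(ann$duration_s <= 0)
  if (length(bad)) {
    stop_if_not(FALSE, "annotation row ", bad[1],
                ": duration_s must be > 0 (got ", ann$duration_s[bad[1]], ")",
                class = "eegannot_validation_error")
  }
  bad <- which(ann$onset_s < 0)
  if (length(bad)) {
    stop_if_not(FALSE, "annotation row ", bad[1], ": onset_s must be >= 0",
                class = "eegannot_validation_error")
  }
  if (!is.null(duration_s)) {
    bad <- which(ann$onset_s + ann$duration_s > duration_s + 1e-9)
    if (length(bad)) {
      stop_if_not(FALSE, "annotation row ", bad[1],
                  " extends past the recording end",
                  class = "eegannot_validation_error")
    }
  }
  ann <- ann[order(ann$onset_s, ann$duration_s), , drop = FALSE]
  rownames(ann) <- NULL
  ann$label <- as.character(ann$label)
  ann
}

#' Write / read a recording in the native container format
#'
#' The native format is a pair of files: a JSON header (`<base>.json`) holding
#' ids, sampling rate and channel names, and a raw little-endian float32 array
#' (`<base>.f32`) with the signal stored sample-major within channel (the
#' column-major layout of the channels x samples matrix). Annotations, if any,
#' go to `<base>_annotations.csv` in the package's annotation CSV dialect.
#' Float32 storage bounds the round-trip error at the 32-bit quantisation
#' level (relative ~2^-24) without the 16-bit dynamic-range loss of EDF.
#'
#' @param rec an `eeg_recording`.
#' @param path path to the JSON header; must end in `.json`.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an `eeg_recording`.
#' @export
write_recording <- function(rec, path) {
  stop_if_not(inherits(rec, "eeg_recording"), "`rec` must be an eeg_recording")
  stop_if_not(grepl("\\.json$", path), "`path` must end in .json",
              class = "eegannot_format_error")
  base <- sub("\\.json$", "", path)
  header <- list(format = "eegannot-recording", version = 1L,
                 subject_id = rec$subject_id, recording_id = rec$recording_id,
                 sr = rec$sr, channel_names = rec$channel_names,
                 n_channels = nrow(rec$signal), n_samples = ncol(rec$signal),
                 dtype = "float32", byte_order = "little")
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA), path)
  con <- file(paste0(base, ".f32"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(rec$signal), con, size = 4L, endian = "little")
  if (nrow(rec$annotations) > 0) {
    write_annotations(rec$annotations, paste0(base, "_annotations.csv"))
  }
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  stop_if_not(file.exists(path), "file not found: ", path)
  stop_if_not(grepl("\\.json$", path),
              "unknown recording format (expected a .json header): ", path,
              class = "eegannot_format_error")
  header <- jsonlite::fromJSON(path)
  stop_if_not(identical(header$format, "eegannot-recording"),
              "not an eegannot recording header: ", path,
              class = "eegannot_format_error")
  base <- sub("\\.json$", "", path)
  f32 <- paste0(base, ".f32")
  stop_if_not(file.exists(f32), "missing signal file: ", f32)
  n <- header$n_channels * header$n_samples
  stop_if_not(file.size(f32) == 4 * n,
              "signal file size does not match the header channel/sample counts",
              class = "eegannot_integrity_error")
  con <- file(f32, "rb")
  on.exit(close(con), add = TRUE)
  x <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  ann_path <- paste0(base, "_annotations.csv")
  ann <- if (file.exists(ann_path)) read_annotations(ann_path) else NULL
  recording(matrix(x, nrow = header$n_channels),
            sr = header$sr,
            channel_names = header$channel_names,
            subject_id = header$subject_id,
            recording_id = header$recording_id,
            annotations = ann)
}

#' Read / write artifact annotation intervals
#'
#' Plain CSV with header `onset_s,duration_s,label`; times are seconds from
#' recording start, intervals are half-open `[onset, onset + duration)`.
#' Intervals are stored and returned sorted by onset; numbers are written in
#' shortest exact decimal form so write -> read -> write is byte-identical.
#'
#' @param path CSV path.
#' @param ann annotation data frame.
#' @return `read_annotations` returns the validated, onset-sorted data frame.
#' @export
read_annotations <- function(path) {
  stop_if_not(file.exists(path), "file not found: ", path)
  ann <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(onset_s = "numeric",
                                        duration_s = "numeric",
                                        label = "character"))
  validate_annotations(ann)
}

#' @rdname read_annotations
#' @export
write_annotations <- function(ann, path) {
  ann <- validate_annotations(ann)
  write_csv_canonical(ann, path, numeric_cols = c("onset_s", "duration_s"))
  invisible(path)
}

# canonical CSV writer: unquoted, LF, shortest exact numeric strings
write_csv_canonical <- function(df, path, numeric_cols = character(0)) {
  out <- df
  for (cl in numeric_cols) out[[cl]] <- format_num(df[[cl]])
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  lines <- c(paste(names(out), collapse = ","),
             if (nrow(out)) do.call(paste, c(unname(as.list(out)), sep = ",")))
  writeLines(lines, con, sep = "\n")
}

#' Read / write segment label tables
#'
#' Columns: `segment_id`, `recording_id`, `subject_id`, `onset_s`, `label`.
#' @param seg segment table data frame.
#' @param path CSV path.
#' @export
write_segment_table <- function(seg, path) {
  cols <- c("segment_id", "recording_id", "subject_id", "onset_s", "label")
  stop_if_not(all(cols %in% names(seg)), "segment table needs columns: ",
              paste(cols, collapse = ", "))
  write_csv_canonical(seg[, cols], path, numeric_cols = "onset_s")
  invisible(path)
}

#' @rdname write_segment_table
#' @export
read_segment_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(segment_id = "character",
                                 recording_id = "character",
                                 subject_id = "character",
                                 onset_s = "numeric", label = "character"))
}

#' Read / write per-segment prediction tables
#'
#' Columns: `segment_id`, `p_artifact` (the model's artifact probability).
#' @param pred prediction data frame.
#' @param path CSV path.
#' @export
write_predictions <- function(pred, path) {
  stop_if_not(all(c("segment_id", "p_artifact") %in% names(pred)),
              "prediction table needs columns segment_id, p_artifact")
  write_csv_canonical(pred[, c("segment_id", "p_artifact")], path,
                      numeric_cols = "p_artifact")
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(segment_id = "character",
                                 p_artifact = "numeric"))
}

#' Read / write rater decision tables
#'
#' Columns: `segment_id`, `rater`, `decision` with decisions in
#' `keep`, `artifact`, `nonartifact`, `uncertain`, `gray`.
#' @param dec decision data frame.
#' @param path CSV path.
#' @export
write_rater_decisions <- function(dec, path) {
  cols <- c("segment_id", "rater", "decision")
  stop_if_not(all(cols %in% names(dec)),
              "decision table needs columns segment_id, rater, decision")
  ok <- dec$decision %in% c("keep", "artifact", "nonartifact", "uncertain", "gray")
  stop_if_not(all(ok), "invalid decision value: ",
              paste(unique(dec$decision[!ok]), collapse = ", "),
              class = "eegannot_validation_error")
  write_csv_canonical(dec[, cols], path)
  invisible(path)
}

#' @rdname write_rater_decisions
#' @export
read_rater_decisions <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(segment_id = "character",
                                 rater = "character",
                                 decision = "character"))
}
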