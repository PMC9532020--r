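#' Per-sample artifact probability trace
#'
#' Converts overlapping-window predictions (1-s windows on the 0.5-s onset
#' grid) into one probability value per time sample for display alongside
#' the signal. Each sample takes the arithmetic mean of the three windows
#' whose centres are nearest in time (the current window plus its
#' predecessor and successor); samples in the first and last second of the
#' recording, where no three overlapping windows exist, use the nearest
#' two. Each sample also gets one of five probability categories.
#'
#' @param predictions data frame with `onset_s` and `p_artifact` covering
#'   every window of the recording.
#' @param duration_s recording duration in seconds.
#' @param trace_sr sample rate of the trace, Hz.
#' @param step_s window onset grid step.
#' @param window_s window length.
#' @return A data frame (`class trace`) with `t` (seconds), `p` and
#'   `category` per trace sample.
#' @export
interpolate_trace <- function(predictions, duration_s, trace_sr = 100,
                              step_s = 0.5, window_s = 1.0) {
  expected <- window_onsets(duration_s,
                            label_rule(window_s = window_s,
                                       overlap = 1 - step_s / window_s))
  ord <- order(predictions$onset_s)
  onsets <- predictions$onset_s[ord]
  stop_if_not(length(onsets) == length(expected) &&
                max(abs(onsets - expected)) < 1e-9,
              "predictions must cover every window of the recording",
              class = "eegannot_coverage_error")
  p <- predictions$p_artifact[ord]
  centres <- onsets + window_s / 2
  n <- floor(duration_s * trace_sr)
  t <- (seq_len(n) - 1) / trace_sr
  edge <- t < 1 | t >= duration_s - 1
  pt <- vapply(seq_len(n), function(i) {
    k <- if (edge[i]) 2L else 3L
    use <- order(abs(centres - t[i]), centres)[seq_len(min(k, length(centres)))]
    mean(p[use])
  }, numeric(1))
  out <- data.frame(t = t, p = pt, category = categorize_probability(pt))
  class(out) <- c("trace", "data.frame")
  out
}

#' Five-band probability category
#'
#' Equal-width bins `[0, 0.2)`, `[0.2, 0.4)`, `[0.4, 0.6)`, `[0.6, 0.8)`,
#' `[0.8, 1]` mapped to categories 1..5.
#'
#' @param p probabilities in `[0, 1]`.
#' @return Integer categories 1..5.
#' @export
categorize_probability <- function(p) {
  stop_if_not(all(p >= 0 & p <= 1), "probabilities must be in [0, 1]",
              class = "eegannot_domain_error")
  pmin(as.integer(floor(p / 0.2)) + 1L, 5L)
}

#' Write a probability trace to CSV
#' @param trace a trace data frame from [interpolate_trace()].
#' @param path CSV path.
#' @export
write_trace <- function(trace, path) {
  write_csv_canonical(trace[, c("t", "p", "category")], path,
                      numeric_cols = c("t", "p"))
  invisible(path)
}
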