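#' Design the Hamming-window FIR bandpass filter
#'
#' Linear-phase windowed-sinc bandpass with -6 dB points at the two cutoffs.
#' The number of taps follows the transition-bandwidth rule
#' `n_taps = (3.3 * SR) / TB` rounded up to the nearest even integer, where
#' `TB` is the shorter of the two transition bandwidths. With the default
#' EEG band (0.5-45 Hz, transition bandwidths 0.5 and 11.25 Hz) at
#' 2048 Hz this gives 13,518 taps. Coefficients are scaled to unit gain at
#' the geometric band centre `sqrt(low * high)`.
#'
#' @param sr sampling rate in Hz.
#' @param low,high band edges in Hz.
#' @param tb_low,tb_high transition bandwidths at the two edges, Hz.
#' @return A `filter_spec` with the tap count and coefficients.
#' @export
design_bandpass <- function(sr, low = 0.5, high = 45,
                            tb_low = 0.5, tb_high = 11.25) {
  stop_if_not(tb_low > 0 && tb_high > 0, "transition bandwidths must be > 0",
              class = "eegannot_design_error")
  stop_if_not(low > 0 && low < high, "need 0 < low < high",
              class = "eegannot_design_error")
  stop_if_not(high < sr / 2, "high cutoff must be below the Nyquist frequency",
              class = "eegannot_design_error")
  tb <- min(tb_low, tb_high)
  n_taps <- 2 * ceiling((3.3 * sr) / tb / 2)
  k <- seq_len(n_taps) - 1
  x <- k - (n_taps - 1) / 2                 # half-integers for even n_taps
  f1 <- low / sr
  f2 <- high / sr
  h <- (sin(2 * pi * f2 * x) - sin(2 * pi * f1 * x)) / (pi * x)
  w <- 0.54 - 0.46 * cos(2 * pi * k / (n_taps - 1))
  h <- h * w
  fc <- sqrt(low * high) / sr
  gain <- abs(sum(h * exp(-2i * pi * fc * x)))
  h <- h / gain
  structure(list(sr = sr, low = low, high = high,
                 tb_low = tb_low, tb_high = tb_high,
                 n_taps = n_taps, window = "hamming", coef = h),
            class = "filter_spec")
}

#' Frequency response of a designed filter
#' @param fs a `filter_spec`.
#' @param freqs_hz frequencies at which to evaluate, Hz.
#' @return Complex response values (magnitude = gain).
#' @export
filter_response <- function(fs, freqs_hz) {
  k <- seq_along(fs$coef) - 1
  vapply(freqs_hz, function(f) {
    sum(fs$coef * exp(-2i * pi * f / fs$sr * k))
  }, complex(1))
}

# linear convolution via FFT
fft_conv <- function(x, h) {
  n <- length(x) + length(h) - 1
  nn <- stats::nextn(n)
  X <- stats::fft(c(x, rep(0, nn - length(x))))
  H <- stats::fft(c(h, rep(0, nn - length(h))))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(n)] / nn
}

#' Zero-phase bandpass filtering of a recording
#'
#' Forward FFT convolution with the even-length linear-phase FIR, followed by
#' group-delay compensation (a shift of `floor((n_taps - 1) / 2)` samples;
#' the residual half-sample delay of an even-length filter is left in place,
#' as mandated by the even-rounding tap rule). Edges are reflection-padded so
#' the output has the input's length. Annotations are unchanged.
#'
#' @param rec an [recording()].
#' @param fs a [design_bandpass()] spec (must match the recording's `sr`).
#' @return The filtered recording.
#' @export
apply_bandpass <- function(rec, fs) {
  stop_if_not(inherits(fs, "filter_spec"), "`fs` must be a filter_spec")
  stop_if_not(abs(rec$sr - fs$sr) < 1e-9,
              "filter was designed for a different sampling rate")
  n <- ncol(rec$signal)
  stop_if_not(n > fs$n_taps,
              "recording (", n, " samples) shorter than the filter (",
              fs$n_taps, " taps)", class = "eegannot_length_error")
  pad <- min(fs$n_taps, n - 1)
  delay <- (fs$n_taps - 1) %/% 2
  out <- rec$signal
  for (c in seq_len(nrow(out))) {
    x <- rec$signal[c, ]
    xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
    y <- fft_conv(xp, fs$coef)
    out[c, ] <- y[pad + delay + seq_len(n)]
  }
  rec$signal <- out
  rec
}

#' Select the 19 standard channels
#'
#' Picks the montage channels out of a (possibly higher-density) recording and
#' returns them in the fixed canonical order. Matching is case-insensitive
#' and accepts the modern T7/T8/P7/P8 names for T3/T4/T5/T6.
#'
#' @param rec an [recording()].
#' @param montage ordered channel list (default [standard_montage()]).
#' @return The recording restricted to `montage`, rows in montage order.
#' @export
select_channels <- function(rec, montage = standard_montage()) {
  idx <- match_channels(montage, rec$channel_names)
  if (anyNA(idx)) {
    stop_if_not(FALSE, "montage channels missing from recording: ",
                paste(montage[is.na(idx)], collapse = ", "),
                class = "eegannot_montage_error")
  }
  rec$signal <- rec$signal[idx, , drop = FALSE]
  rec$channel_names <- montage
  rec
}

#' Average re-referencing
#'
#' Subtracts the instantaneous mean across channels from every channel, so the
#' channel mean is zero at each time sample.
#'
#' @param rec an [recording()].
#' @return The re-referenced recording.
#' @export
average_reference <- function(rec) {
  stop_if_not(nrow(rec$signal) >= 2,
              "average reference needs at least 2 channels",
              class = "eegannot_reference_error")
  rec$signal <- sweep(rec$signal, 2, colMeans(rec$signal))
  rec
}

#' Bad-channel interpolation hook
#'
#' Placeholder for spherical-spline interpolation of bad channels. The
#' synthetic generator declares no bad channels, so this hook is the identity;
#' supply an external implementation via `method` to plug one in.
#'
#' @param rec an [recording()].
#' @param bads character vector of bad channel names.
#' @param method optional `function(rec, bads)` performing the interpolation.
#' @return The (possibly interpolated) recording.
#' @export
interpolate_bad_channels <- function(rec, bads = character(0), method = NULL) {
  if (length(bads) == 0) return(rec)
  if (is.null(method)) {
    warning("no interpolation method supplied; returning recording unchanged")
    return(rec)
  }
  method(rec, bads)
}

#' Minimal preprocessing pipeline
#'
#' Bandpass filter, channel selection and average re-referencing, in that
#' order by default. Whether the average reference is computed over all
#' recorded channels or only the 19 retained ones is configurable
#' (`reference_scope`), since both orders are defensible readings of common
#' practice; the default references the selected channels.
#'
#' @param rec an [recording()].
#' @param fs a `filter_spec`, or `NULL` to design the default 0.5-45 Hz filter
#'   at the recording's sampling rate.
#' @param montage channel list for selection, or `NULL` to skip selection.
#' @param reference_scope `"selected"` (re-reference after channel selection)
#'   or `"all"` (before).
#' @return The preprocessed recording.
#' @export
preprocess_recording <- function(rec, fs = NULL, montage = standard_montage(),
                                 reference_scope = c("selected", "all")) {
  reference_scope <- match.arg(reference_scope)
  if (is.null(fs)) fs <- design_bandpass(rec$sr)
  rec <- apply_bandpass(rec, fs)
  if (reference_scope == "all") rec <- average_reference(rec)
  if (!is.null(montage)) rec <- select_channels(rec, montage)
  if (reference_scope == "selected") rec <- average_reference(rec)
  rec
}
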