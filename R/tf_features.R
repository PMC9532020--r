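#' Time-frequency analysis grid
#'
#' 45 logarithmically spaced frequencies spanning 0.5-45 Hz, paired
#' index-wise with 45 logarithmically spaced Morlet envelope widths (FWHM)
#' running from 1.2 s at the lowest frequency down to 0.2 s at the highest,
#' i.e. increasing temporal resolution at higher frequencies.
#'
#' @param n_freqs number of frequency bins.
#' @param f_range frequency range in Hz.
#' @param fwhm_range envelope FWHM range in seconds, ordered (low-frequency
#'   value first).
#' @return A `tf_grid` with `freqs_hz` and `fwhm_s`.
#' @export
tf_grid <- function(n_freqs = 45, f_range = c(0.5, 45),
                    fwhm_range = c(1.2, 0.2)) {
  logspace <- function(a, b, n) exp(seq(log(a), log(b), length.out = n))
  structure(list(freqs_hz = logspace(f_range[1], f_range[2], n_freqs),
                 fwhm_s = logspace(fwhm_range[1], fwhm_range[2], n_freqs)),
            class = "tf_grid")
}

#' Complex Morlet wavelet
#'
#' `w(t) = exp(i 2 pi f t) * exp(-4 ln 2 * t^2 / h^2)` -- a complex
#' exponential under a Gaussian envelope parameterised directly by its
#' time-domain full width at half maximum `h`. The wavelet is amplitude
#' normalised so that convolution with a unit-amplitude sinusoid at `f`
#' yields unit peak power. Support is truncated at +/- 2 FWHM, where the
#' envelope has decayed to 2^-16.
#'
#' @param f centre frequency, Hz.
#' @param fwhm envelope FWHM, seconds.
#' @param sr sampling rate, Hz.
#' @return Complex vector of odd length.
#' @export
morlet_wavelet <- function(f, fwhm, sr) {
  half <- ceiling(2 * fwhm * sr)
  t <- (-half:half) / sr
  env <- exp(-4 * log(2) * t^2 / fwhm^2)
  w <- env * exp(2i * pi * f * t)
  w * (2 / sum(env))
}

#' Morlet wavelet power of a multichannel signal
#'
#' Complex wavelet convolution per channel over the whole signal, returning
#' squared magnitude. Convolving the full recording (rather than isolated 1-s
#' windows) lets the low-frequency wavelets (FWHM up to 1.2 s) be supported
#' without dominant edge effects; segments are sliced from the result
#' afterwards. Set `per_segment = TRUE` in [tensorize_recording()] to get the
#' alternative zero-padded per-segment convolution.
#'
#' @param signal channels x samples numeric matrix.
#' @param grid a [tf_grid()].
#' @param sr sampling rate, Hz.
#' @return Array `n_freqs x n_samples x n_channels` of power values.
#' @export
morlet_power <- function(signal, grid, sr) {
  stop_if_not(is.matrix(signal), "`signal` must be a channels x samples matrix")
  stop_if_not(sr > 2 * max(grid$freqs_hz),
              "sampling rate too low for the requested frequency grid",
              class = "eegannot_parameter_error")
  n <- ncol(signal)
  nc <- nrow(signal)
  nf <- length(grid$freqs_hz)
  wavelets <- lapply(seq_len(nf), function(i) {
    morlet_wavelet(grid$freqs_hz[i], grid$fwhm_s[i], sr)
  })
  maxlen <- max(lengths(wavelets))
  nn <- stats::nextn(n + maxlen - 1)
  wfft <- lapply(wavelets, function(w) stats::fft(c(w, rep(0, nn - length(w)))))
  out <- array(0, dim = c(nf, n, nc))
  for (c in seq_len(nc)) {
    X <- stats::fft(c(signal[c, ], rep(0, nn - n)))
    for (i in seq_len(nf)) {
      y <- stats::fft(X * wfft[[i]], inverse = TRUE) / nn
      centre <- (length(wavelets[[i]]) - 1) / 2
      out[i, , c] <- Mod(y[centre + seq_len(n)])^2
    }
  }
  out
}

#' Resample a 1-s power slice along time
#'
#' Maps a `n_freqs x sr x n_channels` power slice covering exactly one second
#' to `n_out` (default 100) time points by linear interpolation at the
#' `n_out` bin-centre times. Wavelet power is already smoothed by the
#' envelope (FWHM >= 0.2 s), so no further anti-alias filtering is applied;
#' the operator is exact on constant and linearly varying power.
#'
#' @param power array `n_freqs x n_in x n_channels` (or matrix
#'   `n_freqs x n_in`), covering exactly 1 s at `sr = n_in` Hz.
#' @param n_out number of output time points.
#' @return Array `n_freqs x n_out x n_channels`.
#' @export
resample_to_100hz <- function(power, n_out = 100) {
  if (length(dim(power)) == 2) dim(power) <- c(dim(power), 1)
  d <- dim(power)
  n_in <- d[2]
  stop_if_not(n_in >= n_out,
              "input must have at least ", n_out, " samples per second",
              class = "eegannot_length_error")
  # sample i sits at time (i - 0.5) / n_in; query bin centres (k - 0.5) / n_out
  pos <- (seq_len(n_out) - 0.5) / n_out * n_in + 0.5
  i0 <- pmax(1L, pmin(n_in - 1L, floor(pos)))
  frac <- pos - i0
  out <- array(0, dim = c(d[1], n_out, d[3]))
  for (c in seq_len(d[3])) {
    p <- power[, , c, drop = FALSE]
    dim(p) <- d[1:2]
    out[, , c] <- p[, i0, drop = FALSE] * rep(1 - frac, each = d[1]) +
      p[, i0 + 1L, drop = FALSE] * rep(frac, each = d[1])
  }
  out
}

#' Z-score normalise a time-frequency tensor
#'
#' Centres and scales jointly over all channels, frequencies and time points
#' of one segment, giving zero mean and unit standard deviation globally.
#'
#' @param tensor numeric array.
#' @return The normalised array.
#' @export
znormalize <- function(tensor) {
  s <- stats::sd(tensor)
  stop_if_not(is.finite(s) && s > 0,
              "cannot Z-normalise a constant tensor",
              class = "eegannot_normalization_error")
  (tensor - mean(tensor)) / s
}

#' Time-frequency tensors for the segments of a recording
#'
#' Full feature pipeline: Morlet power over the recording, slicing into the
#' labelled 1-s windows, resampling each to 100 time points and Z-scoring
#' per segment. Tensors are returned in `freq x time x channel` layout (the
#' network input convention channels x frequencies x time refers to the same
#' object with channels as the convolution group axis).
#'
#' @param rec a preprocessed [recording()].
#' @param segments segment table for this recording (from
#'   [segment_recording()] or a `segment_dataset`); rows with other
#'   `recording_id`s are ignored.
#' @param grid a [tf_grid()].
#' @param n_time output time points per segment.
#' @param per_segment if `TRUE`, convolve each zero-padded 1-s window in
#'   isolation instead of slicing a whole-recording convolution.
#' @return List with `tensors` (array `n_freqs x n_time x n_channels x
#'   n_segments`) and `segment_id`.
#' @export
tensorize_recording <- function(rec, segments, grid = tf_grid(),
                                n_time = 100, per_segment = FALSE) {
  seg <- segments[segments$recording_id == rec$recording_id, , drop = FALSE]
  nf <- length(grid$freqs_hz)
  nc <- nrow(rec$signal)
  sr <- round(rec$sr)
  out <- array(0, dim = c(nf, n_time, nc, nrow(seg)))
  if (nrow(seg) == 0) return(list(tensors = out, segment_id = character(0)))
  if (per_segment) {
    for (k in seq_len(nrow(seg))) {
      sl <- segment_signal(rec, seg$onset_s[k])
      pw <- morlet_power(sl, grid, rec$sr)
      out[, , , k] <- znormalize(resample_to_100hz(pw, n_time))
    }
  } else {
    pw <- morlet_power(rec$signal, grid, rec$sr)
    for (k in seq_len(nrow(seg))) {
      i0 <- floor(seg$onset_s[k] * rec$sr) + 1
      slice <- pw[, i0:(i0 + sr - 1), , drop = FALSE]
      out[, , , k] <- znormalize(resample_to_100hz(slice, n_time))
    }
  }
  list(tensors = out, segment_id = seg$segment_id)
}

#' Time-frequency tensors for a whole dataset
#'
#' @param recordings list of preprocessed recordings.
#' @param segments combined segment table (e.g. `segment_dataset$segments`).
#' @param ... passed to [tensorize_recording()].
#' @return List with `tensors` (`freq x time x channel x segment`) and
#'   `segment_id` aligned with the table's rows.
#' @export
tensorize_dataset <- function(recordings, segments, ...) {
  parts <- lapply(recordings, tensorize_recording, segments = segments, ...)
  ids <- unlist(lapply(parts, `[[`, "segment_id"))
  d <- dim(parts[[1]]$tensors)
  tensors <- array(0, dim = c(d[1:3], length(ids)))
  at <- 0
  for (p in parts) {
    nk <- length(p$segment_id)
    if (nk > 0) tensors[, , , at + seq_len(nk)] <- p$tensors
    at <- at + nk
  }
  # align to the segment table's order
  m <- match(segments$segment_id, ids)
  stop_if_not(!anyNA(m), "tensorization missed some segments")
  list(tensors = tensors[, , , m, drop = FALSE],
       segment_id = segments$segment_id)
}
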