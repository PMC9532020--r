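test_that("time-frequency grid endpoints and log spacing", {
  g <- tf_grid()
  expect_equal(g$freqs_hz[1], 0.5)
  expect_equal(g$freqs_hz[45], 45)
  expect_equal(g$fwhm_s[1], 1.2)
  expect_equal(g$fwhm_s[45], 0.2)
  # constant ratio between consecutive values
  expect_equal(diff(log(g$freqs_hz)), rep(log(45 / 0.5) / 44, 44))
  expect_equal(diff(log(g$fwhm_s)), rep(log(0.2 / 1.2) / 44, 44))
  # geometric midpoint at the middle bin
  expect_equal(g$freqs_hz[23], sqrt(0.5 * 45), tolerance = 1e-12)
})

test_that("wavelet power localizes a pure sinusoid at the nearest frequency bin", {
  g <- tf_grid()
  sr <- 256
  t <- (0:(8 * sr - 1)) / sr
  x <- matrix(sin(2 * pi * 10 * t), 1)
  pw <- morlet_power(x, g, sr)
  avg <- rowMeans(pw[, (2 * sr):(6 * sr), 1])
  # FFT oracle: the signal's spectral peak, mapped onto the grid
  spec <- Mod(stats::fft(x[1, ]))^2
  f_axis <- (seq_along(spec) - 1) * sr / length(spec)
  f_peak <- f_axis[which.max(spec[f_axis <= sr / 2])]
  expect_identical(which.max(avg), which.min(abs(g$freqs_hz - f_peak)))
  # unit-amplitude sinusoid placed exactly on a grid frequency -> unit peak
  # power there (amplitude normalization)
  f0 <- g$freqs_hz[30]
  x0 <- matrix(sin(2 * pi * f0 * t), 1)
  avg0 <- rowMeans(morlet_power(x0, g, sr)[, (2 * sr):(6 * sr), 1])
  expect_equal(avg0[30], 1, tolerance = 0.02)

  expect_equal(morlet_power(matrix(0, 1, 4 * sr), g, sr),
               array(0, dim = c(45, 4 * sr, 1)))
  expect_error(morlet_power(matrix(0, 1, 256), g, 64),
               class = "eegannot_parameter_error")
})

test_that("FFT convolution agrees with direct time-domain convolution", {
  g <- tf_grid()
  sr <- 128
  set.seed(8)
  x <- rnorm(2 * sr)
  pick <- c(1, 20, 45)
  pw <- morlet_power(matrix(x, 1), tf_grid(), sr)
  for (i in pick) {
    w <- morlet_wavelet(g$freqs_hz[i], g$fwhm_s[i], sr)
    half <- (length(w) - 1) / 2
    xp <- c(rep(0, half), x, rep(0, half))
    direct <- vapply(seq_along(x), function(n) {
      Mod(sum(xp[n:(n + 2 * half)] * rev(w)))^2
    }, numeric(1))
    expect_lt(max(abs(direct - pw[i, , 1])) / max(direct), 1e-6)
  }
})

test_that("time-axis resampling is exact on constants and ramps and yields 100 points", {
  const <- array(3.7, dim = c(2, 2048, 1))
  out <- resample_to_100hz(const)
  expect_equal(dim(out), c(2, 100, 1))
  expect_equal(out, array(3.7, dim = c(2, 100, 1)))

  ramp <- array(rep((seq_len(2048) - 0.5) / 2048, each = 2),
                dim = c(2, 2048, 1))
  rout <- resample_to_100hz(ramp)
  expect_equal(rout[1, , 1], (seq_len(100) - 0.5) / 100, tolerance = 1e-6)

  expect_error(resample_to_100hz(array(0, dim = c(2, 64, 1))),
               class = "eegannot_length_error")
})

test_that("Z-normalization gives global zero mean / unit SD and is idempotent", {
  set.seed(9)
  x <- array(rnorm(45 * 100 * 19, mean = 5, sd = 2), dim = c(45, 100, 19))
  z <- znormalize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  expect_equal(znormalize(z), z, tolerance = 1e-12)
  # agrees with the direct affine transform
  expect_equal(z, (x - mean(x)) / stats::sd(x))
  expect_error(znormalize(array(1, dim = c(2, 2))),
               class = "eegannot_normalization_error")
})

test_that("the feature pipeline maps every 1-s segment to a 45 x 100 x 19 tensor", {
  # 8 s at 256 Hz: long enough for the 1690-tap bandpass at this rate
  cfg <- sim_config(n_subjects = 1, duration_s = 8, sr = 256, seed = 5)
  rec <- preprocess_recording(generate_recording(cfg, 1),
                              fs = design_bandpass(256))
  seg <- segment_recording(rec)
  tz <- tensorize_recording(rec, seg)
  expect_equal(dim(tz$tensors), c(45, 100, 19, nrow(seg)))
  for (k in seq_len(dim(tz$tensors)[4])) {
    expect_equal(mean(tz$tensors[, , , k]), 0, tolerance = 1e-6)
    expect_equal(stats::sd(tz$tensors[, , , k]), 1, tolerance = 1e-6)
  }
  # per-segment (zero-padded) variant produces the same shape
  tz2 <- tensorize_recording(rec, seg[1:2, ], per_segment = TRUE)
  expect_equal(dim(tz2$tensors), c(45, 100, 19, 2))
})

test_that("band power of a stationary signal is stable under a 0.5-s shift", {
  g <- tf_grid()
  sr <- 128
  x <- with_seed(14, matrix(eegannot:::pink_noise(10 * sr, sr, 1), 1))
  pw <- morlet_power(x, g, sr)
  # compare two interior 1-s windows offset by 0.5 s, averaged over bands
  a <- mean(pw[10:40, (4 * sr):(5 * sr), 1])
  b <- mean(pw[10:40, (4.5 * sr):(5.5 * sr), 1])
  expect_lt(abs(a - b) / a, 0.1)
})
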