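#' Configuration for the synthetic resting-EEG generator
#'
#' Generates reproducible 10-20-montage resting EEG with ground-truth artifact
#' intervals so the whole annotation pipeline can be exercised without
#' clinical data. The background is 1/f^beta noise plus a 10-Hz alpha rhythm
#' weighted toward posterior channels; artifacts are drawn from a menu of
#' ocular, muscle, electrode-pop and movement events with Poisson onsets.
#'
#' @param n_subjects number of subjects (one recording each).
#' @param duration_s recording length in seconds (default 180, i.e. the short
#'   end of a typical 3-5 min rest recording).
#' @param sr sampling rate in Hz (default 2048).
#' @param channels channel names (default the 19-channel standard montage).
#' @param background list with `beta` (1/f exponent), `rms` (background RMS in
#'   volts), `alpha_amp` (posterior alpha amplitude, volts), `alpha_hz`.
#' @param artifact_menu list of artifact definitions, see
#'   [default_artifact_menu()].
#' @param seed integer; together with the subject index it fully determines
#'   every recording.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_subjects = 10, duration_s = 180, sr = 2048,
                       channels = standard_montage(),
                       background = list(beta = 1, rms = 20e-6,
                                         alpha_amp = 10e-6, alpha_hz = 10),
                       artifact_menu = default_artifact_menu(),
                       seed = 1) {
  stop_if_not(duration_s > 0, "duration_s must be > 0",
              class = "eegannot_config_error")
  stop_if_not(sr > 0, "sr must be > 0", class = "eegannot_config_error")
  stop_if_not(n_subjects >= 1, "n_subjects must be >= 1",
              class = "eegannot_config_error")
  for (a in artifact_menu) {
    stop_if_not(a$rate >= 0, "artifact rates must be >= 0",
                class = "eegannot_config_error")
    stop_if_not(all(a$duration_range > 0) && diff(a$duration_range) >= 0,
                "artifact duration ranges must be positive and ordered",
                class = "eegannot_config_error")
    stop_if_not(is.null(a$channels) || all(a$channels %in% channels),
                "artifact channel sets must be a subset of the montage",
                class = "eegannot_config_error")
  }
  structure(list(n_subjects = n_subjects, duration_s = duration_s, sr = sr,
                 channels = channels, background = background,
                 artifact_menu = artifact_menu, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default artifact menu
#'
#' Four artifact kinds spanning the physiologic/nonphysiologic taxonomy and
#' the single-channel vs global, slow vs fast patterns a classifier must
#' discriminate:
#' * `ocular` - low-frequency, high-amplitude frontal deflection (blink-like);
#' * `muscle` - 20-45 Hz band-limited burst on temporal channels;
#' * `pop`    - single-channel step/offset (electrode artifact);
#' * `movement` - broadband multi-channel transient.
#'
#' Rates are events per minute; durations are uniform in `duration_range`
#' (seconds); `amp` is the peak scale in volts.
#' @return List of artifact definitions.
#' @export
default_artifact_menu <- function() {
  list(
    list(kind = "ocular", rate = 4, duration_range = c(0.2, 0.5),
         amp = 150e-6,
         channels = c("Fp1", "Fp2", "F7", "F8", "F3", "F4", "Fz")),
    list(kind = "muscle", rate = 3, duration_range = c(0.3, 1.5),
         amp = 50e-6,
         channels = c("T3", "T4", "F7", "F8", "T5", "T6")),
    list(kind = "pop", rate = 1, duration_range = c(0.2, 0.8),
         amp = 200e-6, channels = NULL),  # one random channel per event
    list(kind = "movement", rate = 1, duration_range = c(0.5, 2),
         amp = 100e-6, channels = NULL)   # all channels
  )
}

#' Artifact menu with well-separated class signatures
#'
#' Variant of [default_artifact_menu()] with longer and stronger events
#' (ocular 0.5-1.2 s at 300 uV, muscle 0.6-1.5 s at 100 uV, pop 0.5-1.2 s at
#' 300 uV, movement 0.8-2 s at 200 uV). With the default menu's brief,
#' moderate events, many artifact-labelled windows contain only a 0.1-0.3-s
#' sliver of an event and sit near the class boundary; this menu makes the
#' two classes separate by a clear margin, which is the intended condition
#' for learning-sanity experiments (the margin should be verified, e.g. by
#' comparing within-window signal RMS between the classes). Pop and movement
#' events also occur at 2/min so that every artifact kind has enough
#' training support in short recordings.
#' @return List of artifact definitions.
#' @export
separable_artifact_menu <- function() {
  list(
    list(kind = "ocular", rate = 4, duration_range = c(0.5, 1.2),
         amp = 300e-6,
         channels = c("Fp1", "Fp2", "F7", "F8", "F3", "F4", "Fz")),
    list(kind = "muscle", rate = 3, duration_range = c(0.6, 1.5),
         amp = 100e-6,
         channels = c("T3", "T4", "F7", "F8", "T5", "T6")),
    list(kind = "pop", rate = 2, duration_range = c(0.5, 1.2),
         amp = 300e-6, channels = NULL),
    list(kind = "movement", rate = 2, duration_range = c(0.8, 2),
         amp = 200e-6, channels = NULL)
  )
}

#' Sample the artifact event process for one subject
#'
#' The event layer of the generator, exposed separately so the Poisson event
#' process can be re-run (and checked) independently of waveform rendering.
#' Event onsets are homogeneous Poisson per artifact kind; each event gets a
#' uniform duration from its kind's range and is placed so that it ends
#' within the window-covered part of the recording (so every event of
#' duration >= 0.1 s is guaranteed to produce at least one artifact segment).
#'
#' @param cfg a [sim_config()].
#' @param subject_index subject number in `1..n_subjects`.
#' @return Data frame with `onset_s`, `duration_s`, `label` (the kind) and
#'   `channel` (single affected channel for `pop`, otherwise `NA`), sorted by
#'   onset.
#' @export
sample_artifact_events <- function(cfg, subject_index) {
  stop_if_not(inherits(cfg, "sim_config"), "`cfg` must be a sim_config")
  stop_if_not(subject_index >= 1 && subject_index <= cfg$n_subjects,
              "subject_index out of range")
  d <- cfg$duration_s
  # last point covered by a full 1-s window on the 0.5-s grid
  covered <- if (d >= 1) floor((d - 1) / 0.5) * 0.5 + 1 else d
  with_seed(mix_seed(cfg$seed, subject_index * 10 + 1), {
    evs <- lapply(cfg$artifact_menu, function(a) {
      n_ev <- stats::rpois(1, a$rate / 60 * d)
      if (n_ev == 0) return(NULL)
      dur <- stats::runif(n_ev, a$duration_range[1],
                          min(a$duration_range[2], covered))
      onset <- stats::runif(n_ev, 0, pmax(0, covered - dur))
      chan <- if (a$kind == "pop") {
        sample(cfg$channels, n_ev, replace = TRUE)
      } else rep(NA_character_, n_ev)
      data.frame(onset_s = onset, duration_s = dur, label = a$kind,
                 channel = chan, stringsAsFactors = FALSE)
    })
    evs <- do.call(rbind, evs)
    if (is.null(evs)) {
      evs <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                        label = character(0), channel = character(0),
                        stringsAsFactors = FALSE)
    }
    evs <- evs[order(evs$onset_s, evs$duration_s), , drop = FALSE]
    rownames(evs) <- NULL
    evs
  })
}

# 1/f^beta noise, unit standard deviation
pink_noise <- function(n, sr, beta) {
  w <- stats::rnorm(n)
  wf <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * sr / n
  f <- pmin(f, sr - f)                      # two-sided spectrum
  s <- 1 / pmax(f, 0.1)^(beta / 2)          # 0.1-Hz floor avoids DC blow-up
  s[1] <- 0
  x <- Re(stats::fft(wf * s, inverse = TRUE)) / n
  x / stats::sd(x)
}

# smooth raised-cosine envelope over `n` samples
hann_env <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

render_event <- function(sig, ev, amp, sr, channels) {
  n <- ncol(sig)
  i0 <- floor(ev$onset_s * sr) + 1
  i1 <- min(n, ceiling((ev$onset_s + ev$duration_s) * sr))
  idx <- i0:i1
  len <- length(idx)
  env <- hann_env(len)
  kind <- ev$label
  if (kind == "ocular") {
    # blink-like slow positive deflection, frontal dominance
    w <- amp * env^2
    weights <- stats::setNames(rep(0.05, length(channels)), channels)
    weights[intersect(c("Fp1", "Fp2"), channels)] <- 1
    weights[intersect(c("F7", "F8"), channels)] <- 0.6
    weights[intersect(c("F3", "F4", "Fz"), channels)] <- 0.4
    for (c in seq_along(channels)) {
      sig[c, idx] <- sig[c, idx] + weights[channels[c]] * w
    }
  } else if (kind == "muscle") {
    # band-limited 20-45 Hz burst on temporal channels
    weights <- stats::setNames(rep(0, length(channels)), channels)
    weights[intersect(c("T3", "T4", "F7", "F8"), channels)] <- 1
    weights[intersect(c("T5", "T6"), channels)] <- 0.5
    for (c in which(weights[channels] > 0)) {
      noise <- stats::rnorm(len)
      nf <- stats::fft(noise)
      f <- c(0, seq_len(len - 1)) * sr / len
      f <- pmin(f, sr - f)
      nf[f < 20 | f > 45] <- 0
      burst <- Re(stats::fft(nf, inverse = TRUE)) / len
      s <- stats::sd(burst)
      if (s > 0) burst <- burst / s
      sig[c, idx] <- sig[c, idx] + amp * weights[channels[c]] * env * burst
    }
  } else if (kind == "pop") {
    # single-channel DC offset with 10-ms ramps
    c <- match(ev$channel, channels)
    ramp <- max(1L, min(round(0.01 * sr), floor(len / 2)))
    shape <- c(seq(0, 1, length.out = ramp),
               rep(1, max(0, len - 2 * ramp)),
               seq(1, 0, length.out = ramp))[seq_len(len)]
    sign <- if (stats::runif(1) < 0.5) -1 else 1
    sig[c, idx] <- sig[c, idx] + sign * amp * shape
  } else if (kind == "movement") {
    # broadband transient on every channel, random per-channel gain
    base <- pink_noise(len, sr, beta = 0.5)
    for (c in seq_along(channels)) {
      gain <- stats::runif(1, 0.5, 1)
      sig[c, idx] <- sig[c, idx] + amp * gain * env * base
    }
  }
  sig
}

#' Generate one synthetic EEG recording with ground-truth annotations
#'
#' Deterministic given `(cfg$seed, subject_index)`: the same pair always
#' yields a bit-identical signal and interval list.
#'
#' @param cfg a [sim_config()].
#' @param subject_index subject number in `1..n_subjects`.
#' @return An [recording()] whose `annotations` hold the injected ground-truth
#'   intervals (label = artifact kind; any labelled interval counts as
#'   artifact for segmentation).
#' @export
generate_recording <- function(cfg, subject_index) {
  stop_if_not(inherits(cfg, "sim_config"), "`cfg` must be a sim_config")
  events <- sample_artifact_events(cfg, subject_index)
  n <- round(cfg$duration_s * cfg$sr)
  nc <- length(cfg$channels)
  bg <- cfg$background
  post_w <- stats::setNames(rep(0.1, nc), cfg$channels)
  post_w[intersect(c("O1", "O2"), cfg$channels)] <- 1
  post_w[intersect(c("P3", "P4", "Pz", "T5", "T6"), cfg$channels)] <- 0.6
  sig <- with_seed(mix_seed(cfg$seed, subject_index * 10 + 2), {
    t <- (seq_len(n) - 1) / cfg$sr
    s <- matrix(0, nrow = nc, ncol = n)
    for (c in seq_len(nc)) {
      x <- bg$rms * pink_noise(n, cfg$sr, bg$beta)
      # amplitude-modulated alpha, stronger posteriorly
      mod <- 0.6 + 0.4 * sin(2 * pi * 0.1 * t + stats::runif(1, 0, 2 * pi))
      x <- x + bg$alpha_amp * post_w[c] * mod *
        sin(2 * pi * bg$alpha_hz * t + stats::runif(1, 0, 2 * pi))
      s[c, ] <- x
    }
    amps <- vapply(cfg$artifact_menu, function(a) a$amp, numeric(1))
    names(amps) <- vapply(cfg$artifact_menu, function(a) a$kind, character(1))
    if (nrow(events)) {
      for (k in seq_len(nrow(events))) {
        s <- render_event(s, events[k, ], amps[[events$label[k]]], cfg$sr,
                          cfg$channels)
      }
    }
    s
  })
  recording(sig, sr = cfg$sr, channel_names = cfg$channels,
            subject_id = sprintf("sub%02d", subject_index),
            recording_id = sprintf("sub%02d_rec01", subject_index),
            annotations = events[, c("onset_s", "duration_s", "label")])
}

#' Generate the full synthetic dataset
#'
#' @param cfg a [sim_config()].
#' @return List of [recording()] objects, one per subject.
#' @export
generate_dataset <- function(cfg) {
  lapply(seq_len(cfg$n_subjects), function(i) generate_recording(cfg, i))
}

#' Corrupt a fraction of gold-standard labels
#'
#' Flips a seeded random fraction of artifact/nonartifact labels, emulating
#' an imperfect gold standard whose errors the revision loop should uncover.
#'
#' @param segments segment table with a `label` column.
#' @param fraction fraction of labels to flip.
#' @param seed integer seed.
#' @return List with `segments` (corrupted copy) and `flipped_ids` (the
#'   segment ids whose labels were flipped).
#' @export
corrupt_labels <- function(segments, fraction = 0.1, seed = 1) {
  stop_if_not(fraction >= 0 && fraction <= 1, "fraction must be in [0, 1]")
  n <- nrow(segments)
  flip <- with_seed(mix_seed(seed, 77), sample(n, round(fraction * n)))
  out <- segments
  out$label[flip] <- ifelse(out$label[flip] == "artifact",
                            "nonartifact", "artifact")
  list(segments = out, flipped_ids = segments$segment_id[flip])
}

#' A simulated imperfect rater pair
#'
#' Each rater independently reproduces the true label with probability
#' `p_agree_true`, votes `uncertain` with `p_uncertain`, `gray` with
#' `p_gray`, and otherwise votes the opposite label.
#'
#' @param p_agree_true probability of reproducing the true label.
#' @param p_uncertain,p_gray probabilities of the two non-committal votes.
#' @param seed integer seed.
#' @return A `rater_model` object.
#' @export
rater_model <- function(p_agree_true = 0.9, p_uncertain = 0, p_gray = 0,
                        seed = 1) {
  p <- c(p_agree_true, p_uncertain, p_gray)
  stop_if_not(all(p >= 0 & p <= 1), "probabilities must be in [0, 1]",
              class = "eegannot_config_error")
  stop_if_not(sum(p) <= 1 + 1e-12,
              "p_agree_true + p_uncertain + p_gray must be <= 1",
              class = "eegannot_config_error")
  structure(list(p_agree_true = p_agree_true, p_uncertain = p_uncertain,
                 p_gray = p_gray, seed = as.integer(seed)),
            class = "rater_model")
}

#' Simulate two independent raters over a label sequence
#'
#' @param true_labels character vector in `artifact` / `nonartifact`.
#' @param rm a [rater_model()].
#' @return List with `rater1` and `rater2`, character vectors over
#'   `artifact`, `nonartifact`, `uncertain`, `gray`.
#' @export
simulate_raters <- function(true_labels, rm) {
  stop_if_not(inherits(rm, "rater_model"), "`rm` must be a rater_model")
  stop_if_not(all(true_labels %in% c("artifact", "nonartifact")),
              "true_labels must be 'artifact' or 'nonartifact'")
  n <- length(true_labels)
  flip <- ifelse(true_labels == "artifact", "nonartifact", "artifact")
  one <- function(stream) {
    if (n == 0) return(character(0))
    with_seed(mix_seed(rm$seed, stream), {
      u <- stats::runif(n)
      out <- flip
      out[u < rm$p_agree_true + rm$p_uncertain + rm$p_gray] <- "gray"
      out[u < rm$p_agree_true + rm$p_uncertain] <- "uncertain"
      out[u < rm$p_agree_true] <- true_labels[u < rm$p_agree_true]
      out
    })
  }
  list(rater1 = one(101), rater2 = one(202))
}
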