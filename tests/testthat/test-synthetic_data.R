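test_that("zero artifact rates give an event-free, bit-reproducible recording", {
  menu <- lapply(default_artifact_menu(), function(a) { a$rate <- 0; a })
  cfg <- sim_config(n_subjects = 2, duration_s = 10, sr = 128,
                    artifact_menu = menu, seed = 9)
  rec <- generate_recording(cfg, 1)
  expect_equal(nrow(rec$annotations), 0)
  rec2 <- generate_recording(cfg, 1)
  expect_identical(rec$signal, rec2$signal)
  expect_identical(rec$annotations, rec2$annotations)
  # different subject index -> different draw
  expect_false(identical(generate_recording(cfg, 2)$signal, rec$signal))
})

test_that("injected intervals match an independent run of the event sampler", {
  menu <- list(list(kind = "ocular", rate = 6, duration_range = c(0.3, 0.5),
                    amp = 150e-6, channels = c("Fp1", "Fp2")))
  cfg <- sim_config(n_subjects = 3, duration_s = 60, sr = 128,
                    artifact_menu = menu, seed = 21)
  for (i in 1:3) {
    rec <- generate_recording(cfg, i)
    ev <- sample_artifact_events(cfg, i)
    expect_identical(rec$annotations$onset_s, ev$onset_s)
    expect_identical(rec$annotations$duration_s, ev$duration_s)
  }
  # rate sanity: pooled event count within 4 sd of the Poisson mean 6/min
  total <- sum(vapply(1:3, function(i) nrow(sample_artifact_events(cfg, i)),
                      numeric(1)))
  lambda <- 6 * 3          # 3 subjects x 1 min x 6/min
  expect_lt(abs(total - lambda), 4 * sqrt(lambda))
})

test_that("artifact intervals never extend past the recording boundary", {
  cfg <- sim_config(n_subjects = 5, duration_s = 13.3, sr = 128, seed = 31)
  for (i in 1:5) {
    ev <- sample_artifact_events(cfg, i)
    if (nrow(ev)) expect_true(all(ev$onset_s + ev$duration_s <= 13.3))
  }
})

test_that("artifact-free background is stationary across recording halves", {
  menu <- lapply(default_artifact_menu(), function(a) { a$rate <- 0; a })
  cfg <- sim_config(n_subjects = 1, duration_s = 30, sr = 128,
                    artifact_menu = menu, seed = 13)
  rec <- generate_recording(cfg, 1)
  n <- ncol(rec$signal)
  v1 <- apply(rec$signal[, 1:(n / 2)], 1, var)
  v2 <- apply(rec$signal[, (n / 2 + 1):n], 1, var)
  expect_true(all(pmax(v1, v2) / pmin(v1, v2) < 1.5))
})

test_that("every injected interval of >= 0.1 s yields at least one artifact segment", {
  cfg <- sim_config(n_subjects = 3, duration_s = 20.3, sr = 128, seed = 17)
  for (i in 1:3) {
    rec <- generate_recording(cfg, i)
    seg <- segment_recording(rec)
    art_on <- seg$onset_s[seg$label == "artifact"]
    ev <- rec$annotations[rec$annotations$duration_s >= 0.1, , drop = FALSE]
    for (k in seq_len(nrow(ev))) {
      covered <- any(art_on < ev$onset_s[k] + ev$duration_s[k] &
                       art_on + 1 > ev$onset_s[k])
      expect_true(covered, info = sprintf("subject %d event %d", i, k))
    }
  }
})

test_that("simulated raters reproduce truth at the configured rate", {
  labels <- rep(c("artifact", "nonartifact"), 5000)
  dec <- simulate_raters(labels, rater_model(p_agree_true = 0.9, seed = 2))
  # within 3 binomial standard errors of 0.9
  se <- sqrt(0.9 * 0.1 / 10000)
  expect_lt(abs(mean(dec$rater1 == labels) - 0.9), 3 * se)
  expect_lt(abs(mean(dec$rater2 == labels) - 0.9), 3 * se)
  # deterministic given the seed
  dec2 <- simulate_raters(labels, rater_model(p_agree_true = 0.9, seed = 2))
  expect_identical(dec, dec2)
  expect_identical(simulate_raters(character(0), rater_model()),
                   list(rater1 = character(0), rater2 = character(0)))
})

test_that("rater agreement extremes give the expected Cohen's kappa", {
  labels <- rep(c("artifact", "nonartifact"), 500)
  perfect <- simulate_raters(labels, rater_model(p_agree_true = 1, seed = 3))
  expect_identical(perfect$rater1, labels)
  expect_equal(cohens_kappa(perfect$rater1, perfect$rater2)$kappa, 1)

  # coin-flip raters on balanced labels: chance agreement, kappa ~ 0
  labels <- rep(c("artifact", "nonartifact"), 5000)
  coin <- simulate_raters(labels, rater_model(p_agree_true = 0.5, seed = 4))
  expect_lt(abs(cohens_kappa(coin$rater1, coin$rater2)$kappa), 0.05)
})

test_that("uncertain and gray vote rates follow the rater model", {
  labels <- rep(c("artifact", "nonartifact"), 2500)
  rm <- rater_model(p_agree_true = 0.7, p_uncertain = 0.2, p_gray = 0.05,
                    seed = 6)
  dec <- simulate_raters(labels, rm)
  expect_lt(abs(mean(dec$rater1 == "uncertain") - 0.2), 0.03)
  expect_lt(abs(mean(dec$rater1 == "gray") - 0.05), 0.02)
  expect_error(rater_model(p_agree_true = 0.8, p_uncertain = 0.3),
               class = "eegannot_config_error")
  expect_error(sim_config(duration_s = -1), class = "eegannot_config_error")
})
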