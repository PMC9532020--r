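test_that("subject-wise folds: 80/10/10 split, disjoint sets, determinism", {
  ids <- sprintf("sub%02d", 1:10)
  plan <- make_folds(ids, k = 5, seed = 1)
  held <- list()
  for (f in plan$folds) {
    expect_length(f$train, 8)
    expect_length(f$val, 1)
    expect_length(f$test, 1)
    expect_length(intersect(f$train, c(f$val, f$test)), 0)
    expect_length(intersect(f$val, f$test), 0)
    held[[length(held) + 1]] <- c(f$val, f$test)
  }
  # held-out groups partition the subjects; test sets pairwise disjoint
  expect_setequal(unlist(held), ids)
  expect_equal(anyDuplicated(unlist(held)), 0)
  tests <- unlist(lapply(plan$folds, `[[`, "test"))
  expect_equal(anyDuplicated(tests), 0)

  expect_identical(make_folds(ids, k = 5, seed = 1), plan)
  expect_false(identical(make_folds(ids, k = 5, seed = 2), plan))
  expect_error(make_folds(ids[1:4], k = 5), class = "eegannot_split_error")
})

test_that("class weights are one over the class count", {
  labels <- c(rep("artifact", 100), rep("nonartifact", 300))
  w <- class_weights(labels)
  expect_equal(w, c(artifact = 1 / 100, nonartifact = 1 / 300))
  expect_equal(unname(class_weights(rep(c("artifact", "nonartifact"), 5))),
               c(0.2, 0.2))
  expect_error(class_weights(rep("artifact", 10)),
               class = "eegannot_weight_error")
})

test_that("weighted cross-entropy: zero at perfection, unweighted under equal weights", {
  probs <- rbind(c(1, 0), c(0, 1), c(1, 0))
  y <- c(1L, 2L, 1L)
  w <- c(artifact = 1 / 2, nonartifact = 1)
  expect_equal(eegannot:::weighted_ce(probs, y, w)$loss, 0)
  set.seed(24)
  p1 <- runif(6)
  probs <- cbind(p1, 1 - p1)
  y <- sample(1:2, 6, replace = TRUE)
  eq <- eegannot:::weighted_ce(probs, y, c(artifact = 3, nonartifact = 3))
  expect_equal(eq$loss, mean(-log(probs[cbind(1:6, y)])))
})

test_that("metrics match the confusion-count definitions", {
  # TP=3, FN=1, FP=1, TN=3 -> all four metrics 0.75
  labels <- rep(c("artifact", "nonartifact"), each = 4)
  p <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.1, 0.1, 0.1)
  m <- evaluate_predictions(p, labels)
  expect_equal(m$TP, 3); expect_equal(m$FN, 1)
  expect_equal(m$FP, 1); expect_equal(m$TN, 3)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.75)
  expect_equal(m$precision, 0.75)
  expect_equal(m$bacc, 0.75)
  # bAcc two ways: mean of per-class recalls
  recall_art <- m$TP / (m$TP + m$FN)
  recall_non <- m$TN / (m$TN + m$FP)
  expect_identical(m$bacc, (recall_art + recall_non) / 2)

  perfect <- evaluate_predictions(c(1, 1, 0, 0),
                                  c("artifact", "artifact",
                                    "nonartifact", "nonartifact"))
  expect_equal(perfect$bacc, 1)

  allpos <- evaluate_predictions(rep(1, 4),
                                 c("artifact", "artifact",
                                   "nonartifact", "nonartifact"))
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  expect_equal(allpos$bacc, 0.5)

  expect_warning(evaluate_predictions(c(0.2, 0.7), rep("nonartifact", 2)),
                 "sensitivity")
  # threshold rule: artifact iff p >= threshold
  m2 <- evaluate_predictions(c(0.5, 0.499), c("artifact", "artifact"), 0.5)
  expect_equal(m2$TP, 1)
})

test_that("a single batch can be overfitted to perfect training accuracy", {
  d <- get_demo_data()
  idx <- c(which(d$segments$label == "artifact")[1:32],
           which(d$segments$label == "nonartifact")[1:32])
  x <- d$tensors[, , , idx, drop = FALSE]
  lab <- d$segments$label[idx]
  cfg <- demo_train_config(seed = 3)
  fit <- train_model(build_model(cfg$arch, seed = 3), x, lab, cfg,
                     epochs = 200)
  p <- predict_proba(fit$model, x)
  expect_equal(mean((p >= 0.5) == (lab == "artifact")), 1)
  # training loss collapses far below its starting point
  expect_lt(fit$history$train_loss[200], 0.1 * fit$history$train_loss[1])
})

test_that("cross-validation bookkeeping: per-fold metrics, histories, pooled epoch", {
  cv <- get_cv_result()
  expect_equal(nrow(cv$metrics), 5)
  expect_equal(cv$summary$mean[cv$summary$metric == "bacc"],
               mean(cv$metrics$bacc))
  # each fold trained epochs_cv + 1 pooled epoch
  expect_equal(nrow(cv$history), 5 * (cv$cfg$epochs_cv + 1))
  expect_true(all(is.na(cv$history$val_loss[cv$history$epoch ==
                                              cv$cfg$epochs_cv + 1])))
  # the pooled epoch has no validation loss but a recorded train loss
  expect_true(all(is.finite(cv$history$train_loss)))
  # test confusion counts cover exactly the held-out subjects' segments
  d <- get_demo_data()
  for (f in seq_len(5)) {
    n_test <- sum(d$segments$subject_id %in% cv$plan$folds[[f]]$test)
    m <- cv$metrics[f, ]
    expect_equal(m$TP + m$FN + m$FP + m$TN, n_test)
  }
})

test_that("final full-data training predicts every segment exactly once", {
  rr <- get_revision_result()
  fit <- rr$cycle$fit_before
  d <- get_demo_data()
  expect_setequal(fit$predictions$segment_id, d$segments$segment_id)
  expect_equal(anyDuplicated(fit$predictions$segment_id), 0)
  expect_true(all(fit$predictions$p_artifact >= 0 &
                    fit$predictions$p_artifact <= 1))
  # prediction table round-trips through the io module
  path <- file.path(withr::local_tempdir(), "pred.csv")
  write_predictions(fit$predictions, path)
  expect_equal(read_predictions(path), fit$predictions)
  # training loss decreases over the final fit
  expect_lt(utils::tail(fit$history$train_loss, 1),
            fit$history$train_loss[1])
})
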