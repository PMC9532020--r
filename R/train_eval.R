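#' Training configuration
#'
#' Learning hyperparameters: mini-batches of 64 segments, learning rate
#' 1e-4, averaged stochastic gradient descent (ASGD), class-weighted
#' cross-entropy with weights 1 / class count, decision threshold 0.5,
#' 70 cross-validation epochs and 100 epochs for the final full-data fit.
#' The ASGD constants (`lambda`, `alpha`, `t0`) are the conventional
#' optimizer defaults and are recorded in checkpoints.
#'
#' @param batch_size mini-batch size.
#' @param lr learning rate.
#' @param epochs_cv epochs per cross-validation fold.
#' @param epochs_final epochs for the final full-data training.
#' @param threshold artifact decision threshold on the predicted probability.
#' @param arch an [arch_spec()].
#' @param seed integer seed controlling weight init and batch shuffling.
#' @param lambda,alpha,t0 ASGD decay term, power for the learning-rate
#'   schedule, and averaging start point.
#' @return A `train_config` object.
#' @export
train_config <- function(batch_size = 64, lr = 1e-4, epochs_cv = 70,
                         epochs_final = 100, threshold = 0.5,
                         arch = arch_spec(), seed = 1,
                         lambda = 1e-4, alpha = 0.75, t0 = 1e6) {
  stop_if_not(batch_size >= 1 && lr > 0 && epochs_cv >= 1 && epochs_final >= 1,
              "training configuration values must be positive")
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 epochs_cv = as.integer(epochs_cv),
                 epochs_final = as.integer(epochs_final),
                 threshold = threshold, arch = arch, seed = as.integer(seed),
                 lambda = lambda, alpha = alpha, t0 = t0),
            class = "train_config")
}

#' Subject-wise five-fold cross-validation plan
#'
#' Subjects are partitioned into `k` disjoint held-out groups (20% each for
#' `k = 5`); within each fold the held-out group is split evenly into
#' validation and test halves by a seeded draw and the remaining 80% of
#' subjects form the training set. All recordings of a subject stay on the
#' same side of every split, so no individual's data ever spans train and
#' test.
#'
#' @param subject_ids character vector of subject ids (duplicates allowed;
#'   the unique set is partitioned).
#' @param k number of folds.
#' @param seed integer seed.
#' @return A `fold_plan`: list of `k` folds, each with `train`, `val`,
#'   `test` subject vectors.
#' @export
make_folds <- function(subject_ids, k = 5, seed = 1) {
  ids <- unique(subject_ids)
  stop_if_not(length(ids) >= k, "need at least ", k, " subjects for ", k,
              "-fold cross-validation", class = "eegannot_split_error")
  with_seed(mix_seed(seed, 33), {
    perm <- sample(ids)
    groups <- split(perm, rep_len(seq_len(k), length(perm)))
    folds <- lapply(seq_len(k), function(i) {
      held <- sample(groups[[i]])
      n_test <- ceiling(length(held) / 2)
      list(train = setdiff(ids, held),
           val = held[-seq_len(n_test)],
           test = held[seq_len(n_test)])
    })
    structure(list(folds = folds, k = k, seed = as.integer(seed)),
              class = "fold_plan")
  })
}

#' Class weights for imbalanced training
#'
#' One divided by the number of training examples in the class.
#'
#' @param labels character vector of `artifact` / `nonartifact` labels.
#' @return Named numeric vector `c(artifact = , nonartifact = )`.
#' @export
class_weights <- function(labels) {
  n_art <- sum(labels == "artifact")
  n_non <- sum(labels == "nonartifact")
  stop_if_not(n_art > 0 && n_non > 0,
              "both classes must be present to compute class weights",
              class = "eegannot_weight_error")
  c(artifact = 1 / n_art, nonartifact = 1 / n_non)
}

# class-weighted cross-entropy (mean weighted by per-example class weight,
# the CrossEntropyLoss convention) and its logit gradient
weighted_ce <- function(probs, y_idx, w) {
  n <- nrow(probs)
  wi <- w[y_idx]
  p_true <- probs[cbind(seq_len(n), y_idx)]
  loss <- sum(wi * -log(pmax(p_true, 1e-300))) / sum(wi)
  onehot <- matrix(0, n, ncol(probs))
  onehot[cbind(seq_len(n), y_idx)] <- 1
  dlogits <- (probs - onehot) * (wi / sum(wi))
  list(loss = loss, dlogits = dlogits)
}

# ---- ASGD optimizer ------------------------------------------------------

flatten_params <- function(model) {
  out <- list()
  for (nm in names(model$layers)) {
    out[[paste0(nm, ".W")]] <- model$layers[[nm]]$W
    if (!is.null(model$layers[[nm]]$b)) {
      out[[paste0(nm, ".b")]] <- model$layers[[nm]]$b
    }
  }
  out
}

set_params <- function(model, params) {
  for (nm in names(params)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    model$layers[[parts[1]]][[parts[2]]] <- params[[nm]]
  }
  model
}

asgd_init <- function(model, cfg) {
  params <- flatten_params(model)
  list(step = 0, eta = cfg$lr, mu = 1, lr = cfg$lr, lambda = cfg$lambda,
       alpha = cfg$alpha, t0 = cfg$t0, ax = params)
}

# one ASGD update; returns list(params, state)
asgd_step <- function(params, grads, st) {
  for (nm in names(params)) {
    p <- params[[nm]] * (1 - st$lambda * st$eta)
    p <- p - st$eta * grads[[nm]]
    params[[nm]] <- p
    if (st$mu != 1) {
      st$ax[[nm]] <- st$ax[[nm]] + st$mu * (p - st$ax[[nm]])
    } else {
      st$ax[[nm]] <- p
    }
  }
  st$step <- st$step + 1
  st$eta <- st$lr / (1 + st$lambda * st$lr * st$step)^st$alpha
  st$mu <- 1 / max(1, st$step - st$t0)
  list(params = params, state = st)
}

labels_to_idx <- function(labels) {
  y <- match(labels, c("artifact", "nonartifact"))
  stop_if_not(!anyNA(y), "labels must be 'artifact' or 'nonartifact'")
  y
}

# mean weighted CE over a set, computed in evaluation mode
eval_loss <- function(model, tensors, y_idx, w, batch_size = 256) {
  n <- length(y_idx)
  num <- 0; den <- 0
  for (i0 in seq(1, n, by = batch_size)) {
    idx <- i0:min(n, i0 + batch_size - 1)
    probs <- forward_cnn(model, tensors[, , , idx, drop = FALSE])$probs
    wi <- w[y_idx[idx]]
    p_true <- probs[cbind(seq_along(idx), y_idx[idx])]
    num <- num + sum(wi * -log(pmax(p_true, 1e-300)))
    den <- den + sum(wi)
  }
  num / den
}

#' Train a model on a labelled tensor set
#'
#' Core mini-batch loop: shuffled batches each epoch (seeded), forward pass,
#' class-weighted cross-entropy, backpropagation, ASGD update. Train loss is
#' the running weighted mean over the epoch's batches; validation loss, when
#' a validation set is given, is computed after each epoch with the
#' then-current weights (monitoring only -- no checkpoint selection; the
#' parameters at loop exit are the result).
#'
#' @param model an `eeg_cnn` (modified copy returned).
#' @param tensors array `F x T x C x N` of training inputs.
#' @param labels length-`N` character labels.
#' @param cfg a [train_config()].
#' @param epochs number of epochs.
#' @param weights class weights (default computed from `labels`).
#' @param val optional list(tensors, labels) for validation monitoring.
#' @param opt optional optimizer state to resume from.
#' @param epoch_offset epoch numbering/shuffling offset when resuming.
#' @return List with `model`, `opt` (optimizer state) and `history`
#'   (data frame epoch / train_loss / val_loss).
#' @export
train_model <- function(model, tensors, labels, cfg, epochs,
                        weights = class_weights(labels), val = NULL,
                        opt = NULL, epoch_offset = 0) {
  y <- labels_to_idx(labels)
  n <- length(y)
  if (is.null(opt)) opt <- asgd_init(model, cfg)
  # resume from the optimizer's last iterate (the returned model carries the
  # averaged parameters once the ASGD averaging phase has begun)
  params <- opt$last_params %||% flatten_params(model)
  val_y <- if (!is.null(val)) labels_to_idx(val$labels)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  for (e in seq_len(epochs)) {
    ord <- with_seed(mix_seed(cfg$seed, 1000 + epoch_offset + e), sample(n))
    num <- 0; den <- 0
    for (i0 in seq(1, n, by = cfg$batch_size)) {
      bidx <- ord[i0:min(n, i0 + cfg$batch_size - 1)]
      xb <- tensors[, , , bidx, drop = FALSE]
      model <- set_params(model, params)
      fwd <- forward_cnn(model, xb, training = TRUE)
      ce <- weighted_ce(fwd$probs, y[bidx], weights)
      if (!is.finite(ce$loss)) {
        stop_if_not(FALSE, "training diverged (non-finite loss) at epoch ",
                    e, ", batch starting ", i0,
                    class = "eegannot_training_error")
      }
      grads_nested <- backward_cnn(model, fwd, ce$dlogits)
      grads <- list()
      for (nm in names(params)) {
        parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
        grads[[nm]] <- grads_nested[[parts[1]]][[parts[2]]]
      }
      stepped <- asgd_step(params, grads, opt)
      params <- stepped$params
      opt <- stepped$state
      wsum <- sum(weights[y[bidx]])
      num <- num + ce$loss * wsum
      den <- den + wsum
    }
    # once the ASGD averaging phase has begun, the averaged iterate is the
    # optimizer's estimate; monitor and return it instead of the last iterate
    model <- set_params(model, if (opt$step > opt$t0) opt$ax else params)
    vl <- if (!is.null(val)) {
      eval_loss(model, val$tensors, val_y, weights)
    } else NA_real_
    hist <- rbind(hist, data.frame(epoch = epoch_offset + e,
                                   train_loss = num / den, val_loss = vl))
  }
  opt$last_params <- params
  list(model = set_params(model, if (opt$step > opt$t0) opt$ax else params),
       opt = opt, history = hist)
}

#' Classification metrics at a probability threshold
#'
#' Artifact is the positive class: a segment is predicted `artifact` when
#' its probability is at or above the threshold. Sensitivity
#' `TP / (TP + FN)`, specificity `TN / (TN + FP)`, precision
#' `TP / (TP + FP)` and balanced accuracy (the mean of sensitivity and
#' specificity) are reported together with the confusion counts.
#'
#' @param p_artifact predicted artifact probabilities.
#' @param labels true labels (`artifact` / `nonartifact`).
#' @param threshold decision threshold.
#' @return A `metrics_report` list with `TP`, `FN`, `FP`, `TN`,
#'   `sensitivity`, `specificity`, `precision`, `bacc`.
#' @export
evaluate_predictions <- function(p_artifact, labels, threshold = 0.5) {
  stop_if_not(length(p_artifact) == length(labels),
              "predictions and labels must align")
  pred <- ifelse(p_artifact >= threshold, "artifact", "nonartifact")
  TP <- sum(pred == "artifact" & labels == "artifact")
  FN <- sum(pred == "nonartifact" & labels == "artifact")
  FP <- sum(pred == "artifact" & labels == "nonartifact")
  TN <- sum(pred == "nonartifact" & labels == "nonartifact")
  if (TP + FN == 0) {
    warning("no positive (artifact) examples in truth; sensitivity is NaN")
  }
  sens <- TP / (TP + FN)
  spec <- TN / (TN + FP)
  prec <- TP / (TP + FP)
  structure(list(TP = TP, FN = FN, FP = FP, TN = TN,
                 sensitivity = sens, specificity = spec, precision = prec,
                 bacc = (sens + spec) / 2, threshold = threshold),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("sens %.3f  spec %.3f  prec %.3f  bAcc %.3f  (TP %d FN %d FP %d TN %d)\n",
              x$sensitivity, x$specificity, x$precision, x$bacc,
              x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

#' Evaluate a model on labelled tensors
#' @param model an `eeg_cnn`.
#' @param tensors array `F x T x C x N`.
#' @param labels true labels.
#' @param threshold decision threshold.
#' @return A `metrics_report`.
#' @export
evaluate_model <- function(model, tensors, labels, threshold = 0.5) {
  evaluate_predictions(predict_proba(model, tensors), labels, threshold)
}

#' Subject-wise cross-validated training
#'
#' For each fold: train on the training subjects with per-epoch train and
#' validation losses recorded, then pool train and validation sets for one
#' additional optimisation epoch, and finally score the held-out test
#' subjects at the decision threshold. Class weights are recomputed from
#' each fold's training labels.
#'
#' @param tensors array `F x T x C x N` aligned with `segments` rows.
#' @param segments segment table (`segment_id`, `subject_id`, `label`, ...).
#' @param plan a [make_folds()] plan.
#' @param cfg a [train_config()].
#' @return A `cv_result`: per-fold metrics (`metrics` data frame), loss
#'   curves (`history`), the per-fold fitted models, and a `summary` with
#'   mean and SD of each metric across folds.
#' @export
train_cv <- function(tensors, segments, plan, cfg = train_config()) {
  stop_if_not(dim(tensors)[4] == nrow(segments),
              "tensors and segment table must align")
  rows <- list(); hists <- list(); models <- list()
  for (f in seq_len(plan$k)) {
    fold <- plan$folds[[f]]
    tr <- which(segments$subject_id %in% fold$train)
    va <- which(segments$subject_id %in% fold$val)
    te <- which(segments$subject_id %in% fold$test)
    w <- class_weights(segments$label[tr])
    model <- build_model(cfg$arch, seed = mix_seed(cfg$seed, f))
    fit <- train_model(model, tensors[, , , tr, drop = FALSE],
                       segments$label[tr], cfg, epochs = cfg$epochs_cv,
                       weights = w,
                       val = if (length(va)) list(
                         tensors = tensors[, , , va, drop = FALSE],
                         labels = segments$label[va]))
    # pooled extra epoch on train + validation, same optimizer state
    pool <- c(tr, va)
    loop_history <- fit$history
    fit <- train_model(fit$model, tensors[, , , pool, drop = FALSE],
                       segments$label[pool], cfg, epochs = 1, weights = w,
                       opt = fit$opt, epoch_offset = cfg$epochs_cv)
    fit$history <- rbind(loop_history, fit$history)
    m <- evaluate_model(fit$model, tensors[, , , te, drop = FALSE],
                        segments$label[te], cfg$threshold)
    rows[[f]] <- data.frame(fold = f, sensitivity = m$sensitivity,
                            specificity = m$specificity,
                            precision = m$precision, bacc = m$bacc,
                            TP = m$TP, FN = m$FN, FP = m$FP, TN = m$TN)
    h <- fit$history
    h$fold <- f
    hists[[f]] <- h
    models[[f]] <- fit$model
  }
  metrics <- do.call(rbind, rows)
  summary <- data.frame(
    metric = c("sensitivity", "specificity", "precision", "bacc"),
    mean = vapply(c("sensitivity", "specificity", "precision", "bacc"),
                  function(m) mean(metrics[[m]]), numeric(1)),
    sd = vapply(c("sensitivity", "specificity", "precision", "bacc"),
                function(m) stats::sd(metrics[[m]]), numeric(1)))
  structure(list(metrics = metrics, summary = summary,
                 history = do.call(rbind, hists), models = models,
                 plan = plan, cfg = cfg),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> mean +/- SD over", x$plan$k, "folds\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Final full-data training
#'
#' Trains on the entire dataset without splits (100 epochs by default) and
#' returns the fitted model together with its predictions on the training
#' segments -- the substrate of the revision stage, where confidently
#' misclassified segments are selected for expert re-annotation.
#'
#' @param tensors array `F x T x C x N` aligned with `segments` rows.
#' @param segments segment table.
#' @param cfg a [train_config()].
#' @param epochs override for `cfg$epochs_final`.
#' @return List with `model`, `predictions` (data frame `segment_id`,
#'   `p_artifact`) and `history`.
#' @export
train_final <- function(tensors, segments, cfg = train_config(),
                        epochs = cfg$epochs_final) {
  model <- build_model(cfg$arch, seed = mix_seed(cfg$seed, 999))
  fit <- train_model(model, tensors, segments$label, cfg, epochs = epochs)
  p <- predict_proba(fit$model, tensors)
  list(model = fit$model,
       predictions = data.frame(segment_id = segments$segment_id,
                                p_artifact = p, stringsAsFactors = FALSE),
       history = fit$history)
}
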