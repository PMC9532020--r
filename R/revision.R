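#' Revision selection thresholds
#'
#' Confidently misclassified segments are selected for re-annotation:
#' nonartifact-labelled segments predicted artifact with probability in
#' `[p_fp, 1]` (putative false positives) and artifact-labelled segments
#' predicted with probability in `[0, p_fn]` (putative false negatives),
#' plus, when `include_adjacent`, the immediately preceding and following
#' overlapping windows of every band-selected segment regardless of their
#' predicted probability.
#'
#' @param p_fp lower probability bound for the false-positive band.
#' @param p_fn upper probability bound for the false-negative band.
#' @param include_adjacent include temporal neighbours?
#' @return A `revision_config`.
#' @export
revision_config <- function(p_fp = 0.65, p_fn = 0.40, include_adjacent = TRUE) {
  stop_if_not(p_fn > 0 && p_fn < p_fp && p_fp < 1,
              "need 0 < p_fn < p_fp < 1")
  structure(list(p_fp = p_fp, p_fn = p_fn,
                 include_adjacent = isTRUE(include_adjacent)),
            class = "revision_config")
}

#' Select segments for expert re-annotation
#'
#' @param segments segment table (`segment_id`, `recording_id`, `onset_s`,
#'   `label`).
#' @param predictions data frame `segment_id`, `p_artifact` covering every
#'   segment.
#' @param cfg a [revision_config()].
#' @param step_s onset grid step of the overlapping windows (0.5 s).
#' @return Data frame of candidates: `segment_id`, `recording_id`,
#'   `onset_s`, `label`, `p_artifact`, `reason` in
#'   `fp_band` / `fn_band` / `adjacent`. Neighbours of neighbours are not
#'   added: adjacency closes over band-selected segments only.
#' @export
select_candidates <- function(segments, predictions, cfg = revision_config(),
                              step_s = 0.5) {
  m <- match(segments$segment_id, predictions$segment_id)
  stop_if_not(!anyNA(m), "every segment needs a prediction")
  p <- predictions$p_artifact[m]
  fp <- segments$label == "nonartifact" & p >= cfg$p_fp
  fn <- segments$label == "artifact" & p <= cfg$p_fn
  reason <- rep(NA_character_, nrow(segments))
  reason[fp] <- "fp_band"
  reason[fn] <- "fn_band"
  if (cfg$include_adjacent) {
    band <- which(fp | fn)
    key <- paste(segments$recording_id, round(segments$onset_s / step_s))
    nb_keys <- c(paste(segments$recording_id[band],
                       round(segments$onset_s[band] / step_s) - 1),
                 paste(segments$recording_id[band],
                       round(segments$onset_s[band] / step_s) + 1))
    nb <- which(key %in% nb_keys & is.na(reason))
    reason[nb] <- "adjacent"
  }
  sel <- !is.na(reason)
  out <- data.frame(segment_id = segments$segment_id[sel],
                    recording_id = segments$recording_id[sel],
                    onset_s = segments$onset_s[sel],
                    label = segments$label[sel],
                    p_artifact = p[sel],
                    reason = reason[sel],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)`, where `p_o`
#' is the observed agreement and `p_e = (1 / N^2) * sum_m n_m1 * n_m2` is
#' the chance agreement computed from the raters' marginal category counts.
#' When both raters give one identical constant answer (`p_e = 1`) kappa is
#' undefined and returned as `NA` with band `"undefined"`. The qualitative
#' band follows the conventional scale (e.g. 0.41-0.60 moderate agreement).
#'
#' @param decisions1,decisions2 equal-length categorical vectors.
#' @return A `kappa_result` with `kappa`, `p_o`, `p_e`, marginal counts and
#'   the interpretive `band`.
#' @export
cohens_kappa <- function(decisions1, decisions2) {
  stop_if_not(length(decisions1) == length(decisions2) && length(decisions1) >= 1,
              "need two aligned, non-empty decision sequences")
  n <- length(decisions1)
  cats <- sort(unique(c(decisions1, decisions2)))
  n1 <- table(factor(decisions1, levels = cats))
  n2 <- table(factor(decisions2, levels = cats))
  p_o <- mean(decisions1 == decisions2)
  p_e <- sum(as.numeric(n1) * as.numeric(n2)) / n^2
  kappa <- if (p_e >= 1) NA_real_ else (p_o - p_e) / (1 - p_e)
  structure(list(kappa = kappa, p_o = p_o, p_e = p_e,
                 n_m1 = as.numeric(n1), n_m2 = as.numeric(n2),
                 categories = cats, N = n,
                 band = kappa_band(kappa)),
            class = "kappa_result")
}

kappa_band <- function(k) {
  if (is.na(k)) return("undefined")
  if (k <= 0) "no agreement"
  else if (k <= 0.20) "none to slight"
  else if (k <= 0.40) "fair"
  else if (k <= 0.60) "moderate"
  else if (k <= 0.80) "substantial"
  else "almost perfect"
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (p_o = %.3f, p_e = %.3f, N = %d): %s\n",
              x$kappa, x$p_o, x$p_e, x$N, x$band))
  invisible(x)
}

#' Merge two raters' decisions into revised labels
#'
#' Per segment: a `gray` vote by either rater drops the segment from the
#' dataset entirely; otherwise, when both raters vote the same concrete
#' label (`artifact` / `nonartifact`, with a `keep` vote resolving to the
#' original label) the annotation becomes that label; in every other case --
#' the raters disagree, both are `uncertain`, or one is `uncertain` and the
#' other proposes a change -- the original annotation is kept (replacement
#' requires explicit two-rater agreement). The rule is symmetric in the two
#' raters.
#'
#' @param original character vector of original labels.
#' @param d1,d2 aligned rater decisions in
#'   `keep` / `artifact` / `nonartifact` / `uncertain` / `gray`.
#' @return Data frame with `outcome` (revised label, or `"drop"`), `changed`
#'   and `dropped` flags.
#' @export
merge_decisions <- function(original, d1, d2) {
  stop_if_not(length(original) == length(d1) && length(d1) == length(d2),
              "original labels and both decision vectors must align")
  ok <- c("keep", "artifact", "nonartifact", "uncertain", "gray")
  stop_if_not(all(c(d1, d2) %in% ok), "invalid rater decision")
  r1 <- ifelse(d1 == "keep", original, d1)
  r2 <- ifelse(d2 == "keep", original, d2)
  outcome <- original
  drop <- r1 == "gray" | r2 == "gray"
  agree <- !drop & r1 == r2 & r1 %in% c("artifact", "nonartifact")
  outcome[agree] <- r1[agree]
  outcome[drop] <- "drop"
  data.frame(outcome = outcome,
             changed = !drop & outcome != original,
             dropped = drop,
             stringsAsFactors = FALSE)
}

#' Apply merged revision outcomes to a segment table
#'
#' @param segments segment table.
#' @param merged data frame with `segment_id` and `outcome` (a label or
#'   `"drop"`), covering the revised candidate set.
#' @return List with `segments` (the revised table, dropped rows removed)
#'   and `report` (counts of reviewed, changed and dropped segments and the
#'   class tallies before/after).
#' @export
apply_revision <- function(segments, merged) {
  m <- match(merged$segment_id, segments$segment_id)
  stop_if_not(!anyNA(m), "revision outcome refers to unknown segment(s): ",
              paste(utils::head(merged$segment_id[is.na(m)], 3), collapse = ", "),
              class = "eegannot_integrity_error")
  before <- table(factor(segments$label, levels = c("artifact", "nonartifact")))
  new_label <- segments$label
  new_label[m] <- merged$outcome
  changed <- sum(new_label[m] != segments$label[m] & merged$outcome != "drop")
  keep <- new_label != "drop"
  out <- segments
  out$label <- new_label
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  after <- table(factor(out$label, levels = c("artifact", "nonartifact")))
  list(segments = out,
       report = list(n_reviewed = nrow(merged),
                     n_changed = changed,
                     n_dropped = sum(!keep),
                     counts_before = c(before),
                     counts_after = c(after)))
}

#' One full revision cycle: train, select, re-annotate, merge, retrain
#'
#' Runs the model-guided annotation-improvement loop end to end: fit the
#' final model on the current gold standard, select confidently
#' misclassified segments (plus temporal neighbours), obtain two raters'
#' decisions for them via `rater_fn`, merge the decisions into revised
#' labels, and retrain on the revised gold standard.
#'
#' @param tensors array `F x T x C x N` aligned with `segments`.
#' @param segments segment table (the current gold standard).
#' @param cfg a [train_config()].
#' @param rev_cfg a [revision_config()].
#' @param rater_fn `function(candidates)` returning a data frame with
#'   `segment_id`, `d1`, `d2` rater decisions for the candidate rows (e.g.
#'   wrapping [simulate_raters()] on synthetic data, or reading an expert
#'   decision table via [read_rater_decisions()]).
#' @param epochs epochs for both trainings (default `cfg$epochs_final`).
#' @return List with the pre-revision fit (`fit_before`), `candidates`,
#'   `merged` decisions, `kappa` between the raters, the revision `report`,
#'   the revised `segments`, and the post-revision fit (`fit_after`).
#' @export
revision_cycle <- function(tensors, segments, cfg, rev_cfg = revision_config(),
                           rater_fn, epochs = cfg$epochs_final) {
  fit1 <- train_final(tensors, segments, cfg, epochs = epochs)
  cand <- select_candidates(segments, fit1$predictions, rev_cfg)
  dec <- rater_fn(cand)
  m <- match(cand$segment_id, dec$segment_id)
  stop_if_not(!anyNA(m), "rater_fn must return decisions for every candidate")
  merged <- merge_decisions(cand$label, dec$d1[m], dec$d2[m])
  merged$segment_id <- cand$segment_id
  kap <- if (nrow(cand) > 0) cohens_kappa(dec$d1[m], dec$d2[m])
  rev <- apply_revision(segments, merged)
  keep <- match(rev$segments$segment_id, segments$segment_id)
  fit2 <- train_final(tensors[, , , keep, drop = FALSE], rev$segments, cfg,
                      epochs = epochs)
  list(fit_before = fit1, candidates = cand, merged = merged, kappa = kap,
       report = rev$report, segments = rev$segments, fit_after = fit2)
}

#' Stratify surviving segments by revision outcome
#'
#' Partitions the post-revision dataset into three subsets for performance
#' analysis: `revision_agreed` (reviewed, annotation kept -- including
#' disagreement-kept cases), `revision_changed` (reviewed, annotation
#' replaced) and `non_revised` (never selected). Per-subset metrics of any
#' model can then be computed with [evaluate_predictions()].
#'
#' @param revised_segments revised segment table (from [apply_revision()]).
#' @param candidate_ids segment ids that were selected for revision.
#' @param merged the [merge_decisions()] output, with `segment_id` column.
#' @return Factor vector over `revised_segments` rows with the three levels.
#' @export
stratified_subsets <- function(revised_segments, candidate_ids, merged) {
  subset <- rep("non_revised", nrow(revised_segments))
  reviewed <- revised_segments$segment_id %in% candidate_ids
  subset[reviewed] <- "revision_agreed"
  ch <- merged$segment_id[merged$changed]
  subset[revised_segments$segment_id %in% ch] <- "revision_changed"
  factor(subset,
         levels = c("revision_agreed", "non_revised", "revision_changed"))
}
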