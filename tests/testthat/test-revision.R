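make_seg_table <- function(n, rec = "r1") {
  onsets <- (seq_len(n) - 1) * 0.5
  data.frame(segment_id = sprintf("%s@%06.1f", rec, onsets),
             recording_id = rec, subject_id = "s1", onset_s = onsets,
             label = "nonartifact", stringsAsFactors = FALSE)
}

test_that("candidate selection applies the probability bands and adjacency", {
  seg <- make_seg_table(10)
  seg$label[c(4, 8)] <- "artifact"
  pred <- data.frame(segment_id = seg$segment_id,
                     p_artifact = c(0.1, 0.70, 0.1, 0.9, 0.1,
                                    0.5, 0.1, 0.30, 0.1, 0.1))
  cand <- select_candidates(seg, pred)
  r <- stats::setNames(cand$reason, cand$segment_id)
  # nonartifact with p = 0.70 -> false-positive band
  expect_identical(unname(r[seg$segment_id[2]]), "fp_band")
  # artifact with p = 0.30 -> false-negative band
  expect_identical(unname(r[seg$segment_id[8]]), "fn_band")
  # neighbours of band-selected segments join regardless of probability
  expect_identical(unname(r[seg$segment_id[1]]), "adjacent")
  expect_identical(unname(r[seg$segment_id[3]]), "adjacent")
  expect_identical(unname(r[seg$segment_id[7]]), "adjacent")
  expect_identical(unname(r[seg$segment_id[9]]), "adjacent")
  # artifact with p = 0.9, no selected neighbour -> correct & confident, not selected
  expect_false(seg$segment_id[5] %in% cand$segment_id)
  # adjacency does not close transitively: neighbour-of-neighbour excluded
  expect_false(seg$segment_id[10] %in% cand$segment_id)
  # band membership from a different recording does not leak: r2 is fully
  # correct and confident (artifact p = 0.9, nonartifact p = 0.1)
  seg2 <- seg; seg2$recording_id <- "r2"
  seg2$segment_id <- sub("r1", "r2", seg2$segment_id)
  pred2 <- data.frame(segment_id = seg2$segment_id,
                      p_artifact = ifelse(seg2$label == "artifact", 0.9, 0.1))
  both <- select_candidates(rbind(seg, seg2),
                            rbind(pred, pred2))
  expect_false(any(both$recording_id == "r2"))
})

test_that("Cohen's kappa equals a brute-force contingency evaluation", {
  # 2x2 counts a=45 b=15 c=25 d=15: p_o = 0.60,
  # p_e = (60*70 + 40*30) / 100^2 = 0.54, kappa = 0.06 / 0.46
  d1 <- rep(c("artifact", "artifact", "nonartifact", "nonartifact"),
            c(45, 15, 25, 15))
  d2 <- rep(c("artifact", "nonartifact", "artifact", "nonartifact"),
            c(45, 15, 25, 15))
  k <- cohens_kappa(d1, d2)
  expect_equal(k$p_o, 0.60)
  expect_equal(k$p_e, 0.54)
  expect_equal(k$kappa, 0.06 / 0.46)

  # brute force on random tables with up to 4 categories
  set.seed(15)
  cats <- c("artifact", "nonartifact", "uncertain", "gray")
  for (rep in 1:25) {
    n <- 200
    a <- sample(cats, n, replace = TRUE, prob = runif(4))
    b <- sample(cats, n, replace = TRUE, prob = runif(4))
    brute_po <- sum(a == b) / n
    brute_pe <- 0
    for (m in cats) brute_pe <- brute_pe + (sum(a == m) / n) * (sum(b == m) / n)
    k <- cohens_kappa(a, b)
    expect_equal(k$kappa, (brute_po - brute_pe) / (1 - brute_pe),
                 tolerance = 1e-12)
  }
})

test_that("kappa extremes: self-agreement, independence, relabelling, degeneracy", {
  x <- rep(c("artifact", "nonartifact"), 50)
  expect_equal(cohens_kappa(x, x)$kappa, 1)
  # invariant under category relabelling
  y <- rep(c("nonartifact", "artifact", "artifact", "nonartifact"),
           c(30, 20, 40, 10))
  map <- c(artifact = "A", nonartifact = "B")
  expect_equal(cohens_kappa(x, y)$kappa,
               cohens_kappa(unname(map[x]), unname(map[y]))$kappa)
  # independent raters: near zero
  set.seed(16)
  a <- sample(c("artifact", "nonartifact"), 10000, replace = TRUE)
  b <- sample(c("artifact", "nonartifact"), 10000, replace = TRUE)
  expect_lt(abs(cohens_kappa(a, b)$kappa), 0.05)
  # both raters constant and identical -> undefined
  k <- cohens_kappa(rep("artifact", 5), rep("artifact", 5))
  expect_true(is.na(k$kappa))
  expect_identical(k$band, "undefined")
})

test_that("decision merging follows the replacement / gray / disagreement rules", {
  orig <- c("nonartifact", "artifact", "nonartifact", "artifact",
            "nonartifact", "nonartifact")
  d1 <- c("artifact", "gray", "artifact", "uncertain", "keep", "uncertain")
  d2 <- c("artifact", "artifact", "nonartifact", "uncertain", "keep", "artifact")
  m <- merge_decisions(orig, d1, d2)
  expect_identical(m$outcome,
                   c("artifact",     # both agree on a change -> replaced
                     "drop",         # gray by one rater -> dropped
                     "nonartifact",  # disagreement -> original kept
                     "artifact",     # both uncertain -> original kept
                     "nonartifact",  # both keep -> original
                     "nonartifact")) # uncertain vs change -> original kept
  expect_identical(m$changed, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(m$dropped, c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
  # "keep" votes agreeing with an explicit vote for the original also count
  m2 <- merge_decisions("artifact", "keep", "artifact")
  expect_identical(m2$outcome, "artifact")
  expect_false(m2$changed)
})

test_that("decision merging is symmetric in the raters", {
  set.seed(17)
  opts <- c("keep", "artifact", "nonartifact", "uncertain", "gray")
  orig <- sample(c("artifact", "nonartifact"), 200, replace = TRUE)
  d1 <- sample(opts, 200, replace = TRUE)
  d2 <- sample(opts, 200, replace = TRUE)
  expect_identical(merge_decisions(orig, d1, d2), merge_decisions(orig, d2, d1))
})

test_that("applying revisions updates labels and counts consistently", {
  seg <- make_seg_table(20)
  seg$label[1:6] <- "artifact"
  # no changes
  none <- data.frame(segment_id = seg$segment_id[1:3],
                     outcome = seg$label[1:3], stringsAsFactors = FALSE)
  r <- apply_revision(seg, none)
  expect_identical(r$segments, seg)
  expect_equal(r$report$n_changed, 0)
  # flip one nonartifact to artifact: counts shift by exactly (+1, -1)
  flip <- data.frame(segment_id = seg$segment_id[10], outcome = "artifact")
  r2 <- apply_revision(seg, flip)
  expect_equal(unname(r2$report$counts_after - r2$report$counts_before),
               c(1, -1))
  # unknown segment id -> integrity error
  expect_error(apply_revision(seg, data.frame(segment_id = "nope",
                                              outcome = "artifact")),
               class = "eegannot_integrity_error")
  # randomized outcomes: accounting oracle by brute-force recount
  set.seed(18)
  ids <- sample(seg$segment_id, 12)
  out <- sample(c("artifact", "nonartifact", "drop"), 12, replace = TRUE)
  merged <- data.frame(segment_id = ids, outcome = out)
  r3 <- apply_revision(seg, merged)
  expected <- stats::setNames(seg$label, seg$segment_id)
  expected[ids] <- out
  expected <- expected[expected != "drop"]
  expect_identical(stats::setNames(r3$segments$label, r3$segments$segment_id),
                   expected)
  expect_equal(r3$report$n_dropped, sum(out == "drop"))
})

test_that("revision subsets partition the surviving dataset", {
  seg <- make_seg_table(30)
  seg$label[1:10] <- "artifact"
  cand_ids <- seg$segment_id[5:14]
  merged <- data.frame(segment_id = cand_ids,
                       outcome = c(rep("nonartifact", 3),
                                   seg$label[8:14]),
                       stringsAsFactors = FALSE)
  merged$changed <- merged$outcome != seg$label[5:14]
  r <- apply_revision(seg, merged[, c("segment_id", "outcome")])
  sub <- stratified_subsets(r$segments, cand_ids, merged)
  expect_equal(length(sub), nrow(r$segments))
  expect_equal(sum(sub == "revision_changed"), sum(merged$changed))
  expect_equal(sum(sub == "revision_agreed"), 10 - sum(merged$changed))
  # no revisions -> everything non-revised
  sub0 <- stratified_subsets(seg, character(0),
                             data.frame(segment_id = character(0),
                                        changed = logical(0)))
  expect_true(all(sub0 == "non_revised"))
  # all candidates changed -> agreed subset empty
  all_ch <- merged; all_ch$changed <- TRUE
  sub1 <- stratified_subsets(r$segments, cand_ids, all_ch)
  expect_equal(sum(sub1 == "revision_agreed"), 0)
})
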