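# Brute-force labelling oracle, independent of the package's interval
# arithmetic: discretize time at 0.1-ms steps and count overlap samples per
# interval, then apply the labelling rules to the counted lengths.
oracle_label <- function(onset, intervals, min_int = 0.1, window = 1) {
  if (nrow(intervals) == 0) return("nonartifact")
  dt <- 1e-4
  grid <- seq(onset, onset + window - dt, by = dt) + dt / 2
  per <- vapply(seq_len(nrow(intervals)), function(i) {
    sum(grid >= intervals$onset_s[i] &
          grid < intervals$onset_s[i] + intervals$duration_s[i]) * dt
  }, numeric(1))
  tol <- dt
  if (all(per < tol)) return("nonartifact")
  hit <- per >= min_int - tol |
    (intervals$duration_s <= min_int + 1e-12 & per >= tol)
  if (any(hit)) "artifact" else "ignored"
}
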