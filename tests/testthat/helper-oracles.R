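# Independent oracles and small builders shared across tests.

# All contiguous segmentations of n points with segments of >= m points,
# as lists of segment end indices (exhaustive enumeration).
enumerate_segmentations <- function(n, m) {
  rec <- function(start) {
    if (start > n) return(list(integer(0)))
    out <- list()
    for (end in seq(start + m - 1L, n)) {
      if (n - end > 0 && n - end < m) next
      for (rest in rec(end + 1L)) out <- c(out, list(c(end, rest)))
    }
    out
  }
  rec(1L)
}

# Brute-force optimum of the penalized segmentation objective, scoring each
# segment by -rss/n from an lm() fit (independent of the DP code path).
brute_force_best <- function(x, y, P, m = 3) {
  best <- -Inf
  for (ends in enumerate_segmentations(length(y), m)) {
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    sc <- sum(mapply(function(i, j) {
      -sum(stats::resid(stats::lm(y[i:j] ~ x[i:j]))^2) / (j - i + 1)
    }, starts, ends)) - P * (length(ends) - 1L)
    if (sc > best) best <- sc
  }
  best
}

# Objective value achieved by a segmentation table.
achieved_score <- function(segments, P) {
  sum(-segments$rss / segments$n) - P * (nrow(segments) - 1L)
}

# One-call segmentation + steadiness classification.
classify_trace <- function(trace, config = segmentation_config()) {
  seg <- merge_invalid_segments(dp_segment(trace, config), trace, config)
  classify_steadiness(seg, trace, config)
}
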