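# Independent oracles used across test files.

# Pearson correlation as the explicit standardized-cross-product sum.
pearson_oracle <- function(f, m) {
  n <- length(f)
  sum(((f - mean(f)) / sd(f)) * ((m - mean(m)) / sd(m))) / (n - 1)
}

# Exhaustive centroid-linkage clustering on scalar coordinates: recompute all
# pairwise centroid (mean) distances from scratch at every merge step.
centroid_oracle <- function(coords) {
  clusters <- as.list(seq_along(coords))
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL; best_d <- Inf
    for (a in seq_len(length(clusters) - 1L))
      for (b in (a + 1L):length(clusters)) {
        d <- abs(mean(coords[clusters[[a]]]) - mean(coords[clusters[[b]]]))
        if (d < best_d - 1e-15) { best_d <- d; best <- c(a, b) }
      }
    merges[[length(merges) + 1L]] <-
      list(members = sort(c(clusters[[best[1]]], clusters[[best[2]]])),
           height = best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  merges
}
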