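# Independent oracles, written from the definitions and kept free of any
# package internals so they cannot share a bug with the code under test.

# KS enrichment by explicit evaluation of both running deviations at every
# tag index j, directly from the definition.
ks_oracle <- function(positions, n) {
  v <- sort(positions)
  t <- length(v)
  a_best <- -Inf
  b_best <- -Inf
  for (j in seq_len(t)) {
    a_best <- max(a_best, j / t - v[j] / n)
    b_best <- max(b_best, v[j] / n - (j - 1) / t)
  }
  if (a_best > b_best) a_best else -b_best
}

# Benjamini-Hochberg step-up from first principles: adjusted p for the
# i-th smallest p is min over k >= i of m * p_(k) / k, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  running_min <- Inf
  for (i in rev(seq_len(m))) {
    running_min <- min(running_min, m * p[ord[i]] / i)
    adj_sorted[i] <- min(running_min, 1)
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# a tiny handmade compendium: 6 genes, 3 instances / 2 compounds
tiny_rank_matrix <- function() {
  ranks <- cbind(i1 = c(1L, 2L, 3L, 4L, 5L, 6L),
                 i2 = c(6L, 5L, 4L, 3L, 2L, 1L),
                 i3 = c(2L, 1L, 4L, 3L, 6L, 5L))
  rownames(ranks) <- paste0("g", 1:6)
  meta <- data.frame(instance_id = c("i1", "i2", "i3"),
                     compound = c("drugA", "drugA", "drugB"),
                     dose = "1uM", cell_line = "MCF7",
                     stringsAsFactors = FALSE)
  rank_matrix(ranks, meta)
}

# named rank vector with the given tag positions forced
ranks_with_positions <- function(tags, positions, n) {
  genes <- paste0("g", seq_len(n))
  ranks <- integer(n)
  others <- setdiff(seq_len(n), positions)
  ranks[seq_along(tags)] <- positions
  ranks[(length(tags) + 1L):n] <- others
  names(ranks) <- genes
  ranks
}
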