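# Independent oracles, deliberately written by different means than the
# implementation paths they check.

# Nx/Lx by literal cumulative enumeration.
oracle_nx <- function(lengths, x) {
  sorted <- sort(lengths, decreasing = TRUE)
  total <- sum(sorted)
  acc <- 0
  for (i in seq_along(sorted)) {
    acc <- acc + sorted[i]
    if (acc >= x / 100 * total) {
      return(list(nx = sorted[i], lx = i))
    }
  }
}

# Canonical k-mer multiset by explicit per-position strand enumeration,
# using its own reverse-complement code.
oracle_canonical_kmers <- function(sequence, k) {
  rc1 <- function(s) {
    paste(rev(chartr("ACGTN", "TGCAN",
                     strsplit(s, "", fixed = TRUE)[[1]])), collapse = "")
  }
  n <- nchar(sequence)
  out <- character(0)
  if (n < k) return(out)
  for (i in 1:(n - k + 1)) {
    fwd <- substr(sequence, i, i + k - 1)
    if (grepl("N", fwd, fixed = TRUE)) next
    rc <- rc1(fwd)
    out <- c(out, if (fwd <= rc) fwd else rc)
  }
  out
}

# Greedy primary selection by literal recursion on an adjacency matrix:
# keep the globally longest remaining contig (ties: lexicographically
# smallest id), delete its neighbours, recurse.
oracle_select_primary <- function(adj, lengths, ids) {
  primary <- character(0)
  alive <- rep(TRUE, length(ids))
  while (any(alive)) {
    cand <- which(alive)
    best <- cand[order(-lengths[cand], ids[cand])][1]
    primary <- c(primary, ids[best])
    alive[best] <- FALSE
    alive[adj[best, ] & alive] <- FALSE
  }
  sort(primary)
}

# All maximal independent sets of a small graph, by subset enumeration.
oracle_is_maximal_independent <- function(adj, keep) {
  k <- which(keep)
  if (any(adj[k, k, drop = FALSE])) return(FALSE)  # not independent
  for (v in which(!keep)) {
    if (!any(adj[v, k])) return(FALSE)  # could be added: not maximal
  }
  TRUE
}
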