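# Independent brute-force oracles used across the suite. These avoid the
# package's vectorised machinery on purpose: distances are counted
# character by character and components are grown by breadth-first search.

random_seqs <- function(n, L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

brute_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# all-pairs distance matrix by per-character counting
brute_dist_matrix <- function(seqs) {
  n <- length(seqs)
  D <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) D[i, j] <- D[j, i] <- brute_hamming(seqs[i], seqs[j])
  }
  D
}

# connected components of the <= M graph by BFS over the adjacency matrix
brute_components <- function(D, M) {
  n <- nrow(D)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      nb <- which(D[v, ] <= M & is.na(comp))
      queue <- c(queue, nb)
    }
  }
  comp
}

# canonical form of a partition (list of index sets) for comparison
canonical_partition <- function(groups) {
  sets <- lapply(unname(groups), function(ix) sort(unname(as.integer(ix))))
  sets[order(vapply(sets, `[`, integer(1), 1))]
}

partition_from_membership <- function(comp) {
  canonical_partition(split(seq_along(comp), comp))
}

# flip the given positions to a different base (deterministic)
mut_at <- function(s, pos) {
  for (p in pos) {
    cur <- substr(s, p, p)
    substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  s
}
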