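# Shared fixtures and independent oracles used across test files.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_peptide <- function(n) paste(sample(AA20, n, TRUE), collapse = "")

hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Independent global affine-gap DP (gap of length L costs open + ext * L),
# scores only -- used as the oracle for pairwise_align.
nw_score_oracle <- function(a, b, S, open = 10, ext = 0.5) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + ext * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(open + ext * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
        S[x[i - 1], y[j - 1]]
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Independent local (Smith-Waterman) affine DP score oracle.
sw_score_oracle <- function(a, b, S, open = 10, ext = 0.5) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1); Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                            Y[i - 1, j - 1]) + S[x[i - 1], y[j - 1]])
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Random additive distance matrix from a random tree; returns the matrix.
random_additive_matrix <- function(n_taxa) {
  g <- ape::rtree(n_taxa)
  g$edge.length <- stats::runif(nrow(g$edge), 0.1, 2)
  stats::cophenetic(ape::unroot(g))
}

# Plant two motifs into random background sequences (for motif tests).
plant_two_motifs <- function(n_seqs = 30, len = 120, w1 = 15, w2 = 25) {
  m1 <- random_peptide(w1)
  m2 <- random_peptide(w2)
  seqs <- vapply(seq_len(n_seqs), function(i) {
    bg <- strsplit(random_peptide(len), "")[[1]]
    p1 <- sample(1:(len / 4), 1)
    p2 <- sample(floor(len / 2):(len - w2), 1)
    bg[p1:(p1 + w1 - 1)] <- strsplit(m1, "")[[1]]
    bg[p2:(p2 + w2 - 1)] <- strsplit(m2, "")[[1]]
    paste(bg, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("p%02d", seq_len(n_seqs))
  list(seqs = seqs, m1 = m1, m2 = m2)
}

# Two-stage classification benchmark shared by unit and acceptance tests.
classification_benchmark <- function(divergence, seed,
                                     members_per_group = 4L) {
  b1 <- generate_group_benchmark(n_groups = 8, members_per_group =
                                   members_per_group,
                                 anchors_per_group = 2, n_specific = 0,
                                 seq_length = 120, divergence = divergence,
                                 prefix = "S1", seed = seed)
  b2 <- generate_group_benchmark(n_groups = 4, members_per_group = 3,
                                 anchors_per_group = 2, n_specific = 5,
                                 seq_length = 120, divergence = divergence,
                                 group_labels = c("CCA1-like", "CPC-like",
                                                  "TBP-like", "R-R-type"),
                                 prefix = "S2", seed = seed)
  cand <- c(b1$seqs[!b1$truth$is_anchor], b2$seqs[!b2$truth$is_anchor])
  list(
    candidates = cand,
    anchors1 = list(seqs = b1$seqs[b1$truth$is_anchor],
                    labels = stats::setNames(b1$anchors$group,
                                             b1$anchors$id)),
    anchors2 = list(seqs = b2$seqs[b2$truth$is_anchor],
                    labels = stats::setNames(b2$anchors$group,
                                             b2$anchors$id)),
    truth = rbind(b1$truth, b2$truth))
}
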