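# Ortholog/paralog calling: all-vs-all Smith-Waterman similarity (exact
# local alignment in place of a heuristic search -- the sets here are
# desk-scale), reciprocal best hits, Markov clustering of the similarity
# graph, and pair extraction.

#' All-vs-all local-alignment similarity edges
#'
#' Smith-Waterman score for every cross pair, normalized by the geometric
#' mean of the two self-scores so weights lie in (0, 1] and identical
#' sequences score exactly 1. Edges below `min_score` (raw score) are
#' dropped; the default threshold is the 99th percentile of a seeded
#' shuffled-sequence null.
#'
#' @param seqsA,seqsB named character vectors; pass the same set twice for
#'   within-species edges (self pairs and duplicate orientations are then
#'   dropped).
#' @param substitution_matrix substitution matrix name (default BLOSUM62).
#' @param gap_open,gap_extend affine gap costs.
#' @param min_score numeric threshold on the raw local score, or `"auto"`.
#' @param n_null shuffled pairs used for the automatic threshold.
#' @param seed seed for the shuffled null.
#' @return data frame of edges: `idA`, `idB`, `score`, `weight`.
#' @export
all_vs_all <- function(seqsA, seqsB, substitution_matrix = "BLOSUM62",
                       gap_open = 10, gap_extend = 0.5, min_score = "auto",
                       n_null = 50L, seed = 1L) {
  if (length(seqsA) == 0 || length(seqsB) == 0) {
    stop("both sequence sets must be non-empty")
  }
  within <- identical(seqsA, seqsB)
  score_set <- function(patterns, subject) {
    as.numeric(Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
      substitutionMatrix = substitution_matrix, gapOpening = gap_open,
      gapExtension = gap_extend, type = "local")))
  }
  selfA <- vapply(seqsA, function(s) score_set(s, s), numeric(1))
  selfB <- if (within) selfA else
    vapply(seqsB, function(s) score_set(s, s), numeric(1))
  if (identical(min_score, "auto")) {
    min_score <- with_seed(derive_seed(seed, "homology_null"), {
      null_scores <- vapply(seq_len(n_null), function(i) {
        a <- paste(sample(strsplit(seqsA[[sample.int(length(seqsA), 1)]],
                                   "")[[1]]), collapse = "")
        b <- paste(sample(strsplit(seqsB[[sample.int(length(seqsB), 1)]],
                                   "")[[1]]), collapse = "")
        score_set(a, b)
      }, numeric(1))
      stats::quantile(null_scores, 0.99, names = FALSE)
    })
  }
  rows <- list()
  for (j in seq_along(seqsB)) {
    sc <- score_set(seqsA, seqsB[[j]])
    keep <- which(sc >= min_score)
    if (within) keep <- keep[keep > j]   # dedupe and drop self pairs
    if (length(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        idA = names(seqsA)[keep], idB = names(seqsB)[j],
        score = sc[keep],
        weight = sc[keep] / sqrt(selfA[keep] * selfB[j]),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(idA = character(0), idB = character(0),
               score = numeric(0), weight = numeric(0))
  rownames(out) <- NULL
  out
}

#' Reciprocal best hits between two species
#'
#' A pair (a, b) is kept iff b is a's unique maximum-weight partner and a
#' is b's; any tie for best disqualifies the pair (conservative).
#'
#' @param edges bipartite edge data frame (`idA`, `idB`, `weight`).
#' @return data frame of RBH pairs (`idA`, `idB`, `weight`).
#' @export
rbh <- function(edges) {
  if (nrow(edges) == 0) {
    return(data.frame(idA = character(0), idB = character(0),
                      weight = numeric(0)))
  }
  best_of <- function(key, other) {
    res <- lapply(split(edges, edges[[key]]), function(sub) {
      mx <- max(sub$weight)
      hits <- sub[[other]][sub$weight == mx]
      if (length(hits) == 1) hits else NA_character_
    })
    unlist(res)
  }
  bestA <- best_of("idA", "idB")   # a -> its unique best b
  bestB <- best_of("idB", "idA")
  keep <- vapply(seq_len(nrow(edges)), function(i) {
    a <- edges$idA[i]; b <- edges$idB[i]
    !is.na(bestA[[a]]) && !is.na(bestB[[b]]) &&
      bestA[[a]] == b && bestB[[b]] == a
  }, logical(1))
  out <- edges[keep, c("idA", "idB", "weight"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Markov clustering of a weighted graph
#'
#' Column-stochastic transition matrix with unit self-loops; iterates
#' expansion (matrix square) and inflation (elementwise power, column
#' renormalization) with pruning of small entries until the matrix is
#' stable. Clusters are the connected components of the limit matrix's
#' support.
#'
#' @param edges data frame (`idA`, `idB`, `weight`) or square adjacency
#'   matrix with dimnames.
#' @param inflation inflation exponent (default 2.0; typical range
#'   1.5-4).
#' @param max_iter iteration cap; hitting it returns the current partition
#'   with a warning and `converged = FALSE`.
#' @param prune_threshold entries below this are zeroed each iteration.
#' @param tol convergence threshold on the max absolute change.
#' @return list with `membership` (named integer vector of cluster ids),
#'   `clusters` (list of character vectors), `iterations`, `converged`.
#' @export
mcl <- function(edges, inflation = 2.0, max_iter = 100L,
                prune_threshold = 1e-5, tol = 1e-6) {
  if (is.data.frame(edges)) {
    nodes <- sort(unique(c(edges$idA, edges$idB)))
    A <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    for (i in seq_len(nrow(edges))) {
      A[edges$idA[i], edges$idB[i]] <- edges$weight[i]
      A[edges$idB[i], edges$idA[i]] <- edges$weight[i]
    }
  } else {
    A <- as.matrix(edges)
    stopifnot(nrow(A) == ncol(A), !is.null(rownames(A)))
    nodes <- rownames(A)
  }
  diag(A) <- 1
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M2 <- M %*% M          # expansion
    M2 <- M2 ^ inflation   # inflation
    M2[M2 < prune_threshold] <- 0
    M2 <- sweep(M2, 2, pmax(colSums(M2), .Machine$double.eps), "/")
    if (max(abs(M2 - M)) < tol) {
      M <- M2; converged <- TRUE; break
    }
    M <- M2
  }
  if (!converged) {
    warning("MCL did not converge within ", max_iter, " iterations; ",
            "returning the current partition")
  }
  # connected components of the support
  supp <- (M > 0) | (t(M) > 0)
  n <- nrow(supp)
  membership <- rep(NA_integer_, n)
  cl <- 0L
  for (s in seq_len(n)) {
    if (!is.na(membership[s])) next
    cl <- cl + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(membership[v])) next
      membership[v] <- cl
      queue <- c(queue, which(supp[v, ] & is.na(membership)))
    }
  }
  names(membership) <- nodes
  list(membership = membership,
       clusters = split(nodes, membership),
       iterations = it, converged = converged)
}

#' Call ortholog and paralog pairs from clusters and edges
#'
#' Ortholog pairs are reciprocal best hits whose two ends fall in the same
#' cluster. Paralog pairs are same-species edges within a cluster whose
#' weight reaches the mean cross-species weight of that cluster (clusters
#' without cross-species edges keep all their within-species edges).
#'
#' @param clusters result of [mcl()] (or a named membership vector).
#' @param edges full edge data frame (`idA`, `idB`, `weight`), cross- and
#'   within-species combined.
#' @param rbh_pairs result of [rbh()] on the cross-species edges.
#' @param species named character vector: protein id -> species tag.
#' @return list with `orthologs` (idA, idB, weight, cluster) and
#'   `paralogs` (idA, idB, weight, cluster, species).
#' @export
call_pairs <- function(clusters, edges, rbh_pairs, species) {
  membership <- if (is.list(clusters)) clusters$membership else clusters
  miss <- setdiff(unique(c(edges$idA, edges$idB)), names(species))
  if (length(miss)) {
    stop("species tag missing for: ", paste(miss, collapse = ", "))
  }
  # orthologs: RBH pairs sharing a cluster
  orth <- rbh_pairs
  orth$cluster <- membership[orth$idA]
  same <- !is.na(orth$cluster) &
    membership[orth$idB] == orth$cluster
  orth <- orth[same, , drop = FALSE]
  # paralogs: within-species edges inside a cluster, weight >= mean
  # cross-species weight of the cluster
  e <- edges
  e$clA <- membership[e$idA]; e$clB <- membership[e$idB]
  e <- e[!is.na(e$clA) & !is.na(e$clB) & e$clA == e$clB, , drop = FALSE]
  e$spA <- species[e$idA]; e$spB <- species[e$idB]
  par_rows <- list()
  for (cl in unique(e$clA)) {
    sub <- e[e$clA == cl, , drop = FALSE]
    cross <- sub[sub$spA != sub$spB, , drop = FALSE]
    thr <- if (nrow(cross)) mean(cross$weight) else -Inf
    within <- sub[sub$spA == sub$spB & sub$weight >= thr, , drop = FALSE]
    if (nrow(within)) {
      par_rows[[length(par_rows) + 1L]] <- data.frame(
        idA = within$idA, idB = within$idB, weight = within$weight,
        cluster = cl, species = within$spA, stringsAsFactors = FALSE)
    }
  }
  paral <- if (length(par_rows)) do.call(rbind, par_rows) else
    data.frame(idA = character(0), idB = character(0), weight = numeric(0),
               cluster = integer(0), species = character(0))
  rownames(orth) <- rownames(paral) <- NULL
  list(orthologs = orth, paralogs = paral)
}
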