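# Neighbor-joining (Saitou-Nei) tree construction and nonparametric
# bootstrap supports. The NJ agglomeration is authored here -- including
# the deterministic tie-break and the negative-branch clamping rule -- and
# returns a standard ape "phylo" object, so all downstream tree handling
# (Newick I/O, patristic distances, bipartitions) uses ape.

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: iteratively joins the pair (i, j) minimizing
#' `Q(i, j) = (n - 2) d(i, j) - R_i - R_j` (R = row sums). Branch lengths
#' use the standard split formula; a negative length is clamped to zero
#' with the deficit transferred to its sibling branch, which preserves the
#' joined pair's path length. Ties on Q are broken deterministically by the
#' label-sorted pair. The result is unrooted (trifurcating root node).
#'
#' @param D symmetric distance matrix with labelled rows/columns (n >= 3).
#' @return an object of class `phylo`.
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  n <- nrow(D)
  if (n < 3) stop("neighbor-joining needs at least 3 taxa")
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- sprintf("t%d", seq_len(n))
  }
  if (max(abs(D - t(D))) > 1e-8) stop("D must be symmetric")
  if (any(!is.finite(D))) stop("D must be finite")
  if (any(diag(D) != 0)) stop("D must have a zero diagonal")

  labels <- rownames(D)
  # each active cluster carries a Newick fragment and its smallest member
  # label (the deterministic tie-break key)
  frag <- stats::setNames(labels, labels)
  key <- stats::setNames(labels, labels)
  Dm <- D
  while (nrow(Dm) > 3) {
    m <- nrow(Dm)
    R <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    idx <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    # tie-break: lexicographically smallest (sorted) pair of cluster keys
    pair_keys <- apply(idx, 1, function(r) {
      k <- sort(c(key[[rownames(Dm)[r[1]]]], key[[rownames(Dm)[r[2]]]]))
      paste(k, collapse = "\r")
    })
    pick <- idx[order(pair_keys)[1], ]
    i <- rownames(Dm)[pick[1]]; j <- rownames(Dm)[pick[2]]
    dij <- Dm[i, j]
    li <- dij / 2 + (R[[i]] - R[[j]]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_lab <- paste0("(", frag[[i]], ":", format(li, digits = 12),
                      ",", frag[[j]], ":", format(lj, digits = 12), ")")
    others <- setdiff(rownames(Dm), c(i, j))
    dnew <- (Dm[i, others] + Dm[j, others] - dij) / 2
    Dm2 <- rbind(cbind(Dm[others, others, drop = FALSE], dnew),
                 c(dnew, 0))
    nid <- paste0("u", m)
    rownames(Dm2) <- colnames(Dm2) <- c(others, nid)
    frag[[nid]] <- new_lab
    key[[nid]] <- min(key[[i]], key[[j]])
    Dm <- Dm2
  }
  # final three clusters: three-point branch lengths
  a <- rownames(Dm)[1]; b <- rownames(Dm)[2]; c3 <- rownames(Dm)[3]
  la <- (Dm[a, b] + Dm[a, c3] - Dm[b, c3]) / 2
  lb <- Dm[a, b] - la
  lc <- Dm[a, c3] - la
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  nwk <- paste0("(", frag[[a]], ":", format(la, digits = 12),
                ",", frag[[b]], ":", format(lb, digits = 12),
                ",", frag[[c3]], ":", format(lc, digits = 12), ");")
  ape::read.tree(text = nwk)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds a
#' tree per replicate with `treebuilder`, and scores each internal edge of
#' the original tree by the percentage of replicate trees containing the
#' same bipartition. Supports are attached as `node.label`.
#'
#' @param alignment named character vector of equal-length gapped sequences.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed for the column resampling.
#' @param treebuilder function mapping an alignment to a `phylo`; default
#'   p-distance + [nj_tree()].
#' @return list with `tree` (the original tree with `node.label` set to
#'   supports, in percent) and `supports` (numeric vector, one per internal
#'   node).
#' @export
bootstrap_supports <- function(alignment, n_reps = 100L, seed = 1L,
                               treebuilder = function(aln)
                                 nj_tree(distance_matrix(aln))) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  width <- unique(nchar(alignment))
  if (length(width) != 1) stop("ragged alignment")
  if (width == 0) stop("alignment width is zero")
  mat <- do.call(rbind, strsplit(alignment, ""))
  rownames(mat) <- names(alignment)
  orig <- treebuilder(alignment)
  reps <- with_seed(derive_seed(seed, "bootstrap"), {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(width, width, replace = TRUE)
      sub <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
      treebuilder(stats::setNames(sub, rownames(mat)))
    })
  })
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(orig, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  supports <- 100 * counts / n_reps
  orig$node.label <- format_num(supports, 4)
  list(tree = orig, supports = supports)
}
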