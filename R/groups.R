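# Anchor-guided group assignment on a neighbor-joining tree, and the
# two-stage classification used for large plant MYB families: stage 1
# classifies candidates against R2R3/R1R2R3 reference anchors into
# C-groups; whatever stays unlabelled is re-analysed in stage 2 against
# 1R/4R/atypical anchors, and what clusters with no reference at all is
# called species-specific.
#
# The published practice of drawing group boundaries on a figure by eye is
# replaced by a deterministic rule: each query takes the majority anchor
# label of the smallest edge-bounded clade that contains it and at least
# one anchor, unless its nearest anchor is too far (patristic distance
# above a calibrated multiple of the within-group anchor spread), in which
# case it is species-specific.

#' Assign phylogenetic group labels to queries on an anchored tree
#'
#' For each non-anchor tip, the tree is rooted at that tip and its
#' ancestors are walked outward; the first ancestor whose subtree contains
#' an anchor defines the smallest anchor-containing clade. The query takes
#' the majority anchor label of that clade; label ties are broken by the
#' nearest (patristic) tied anchor, then lexicographically. A query whose
#' nearest anchor exceeds `specific_multiplier` times the
#' `specific_quantile` quantile of within-group anchor-anchor patristic
#' distances is labelled `"species-specific"` instead.
#'
#' @param tree a `phylo`, optionally with bootstrap `node.label`s.
#' @param anchors named character vector: anchor tip label -> group label.
#' @param specific_quantile quantile of within-group anchor-anchor
#'   distances used as the distance scale (default 0.9).
#' @param specific_multiplier safety factor on that scale (default 2);
#'   guards against sampling noise in short alignments pushing ordinary
#'   group members past the raw quantile.
#' @return data frame: `query`, `group`, `support` (bootstrap label of the
#'   clade node, NA when absent), `nearest_anchor`, `nearest_distance`.
#' @export
assign_groups <- function(tree, anchors, specific_quantile = 0.9,
                          specific_multiplier = 2) {
  stopifnot(inherits(tree, "phylo"))
  anchors <- anchors[names(anchors) %in% tree$tip.label]
  if (length(anchors) == 0) stop("tree contains no anchor tips")
  queries <- setdiff(tree$tip.label, names(anchors))
  pat <- ape::cophenetic.phylo(tree)

  # distance scale from anchors that share a group label
  within <- numeric(0)
  for (g in unique(anchors)) {
    ids <- names(anchors)[anchors == g]
    if (length(ids) > 1) {
      within <- c(within, pat[ids, ids][lower.tri(matrix(0, length(ids),
                                                         length(ids)))])
    }
  }
  cutoff <- if (length(within)) {
    specific_multiplier * stats::quantile(within, specific_quantile,
                                          names = FALSE)
  } else Inf

  out <- lapply(queries, function(q) {
    d_anchor <- pat[q, names(anchors)]
    nearest <- names(anchors)[which.min(d_anchor)]
    ndist <- min(d_anchor)
    if (ndist > cutoff) {
      return(data.frame(query = q, group = "species-specific",
                        support = NA_real_, nearest_anchor = nearest,
                        nearest_distance = ndist, stringsAsFactors = FALSE))
    }
    rooted <- ape::root(tree, outgroup = q, resolve.root = TRUE)
    ntip <- length(rooted$tip.label)
    qidx <- match(q, rooted$tip.label)
    parent <- function(node) rooted$edge[rooted$edge[, 2] == node, 1]
    node <- parent(qidx)
    clade_tips <- character(0)
    support <- NA_real_
    while (length(node)) {
      tips <- ape::extract.clade(rooted, node)$tip.label
      hit <- intersect(tips, names(anchors))
      if (length(hit)) {
        clade_tips <- tips
        if (!is.null(rooted$node.label)) {
          lab <- rooted$node.label[node - ntip]
          support <- suppressWarnings(as.numeric(lab))
        }
        break
      }
      node <- parent(node)
    }
    in_clade <- anchors[intersect(clade_tips, names(anchors))]
    tab <- table(in_clade)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      # tie: nearest tied anchor, then lexicographic
      tied <- names(in_clade)[in_clade %in% top]
      ord <- order(pat[q, tied], anchors[tied])
      top <- anchors[[tied[ord[1]]]]
    }
    data.frame(query = q, group = top, support = support,
               nearest_anchor = nearest, nearest_distance = ndist,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-stage anchor-guided classification of family candidates
#'
#' Stage 1 aligns all candidate proteins together with the stage-1 anchor
#' set (R2R3/R1R2R3 references), builds a neighbor-joining tree with
#' bootstrap supports, and assigns C-group labels. Candidates that stage 1
#' leaves species-specific are re-analysed in stage 2 with the second
#' anchor set (1R/4R/atypical references); what remains unanchored after
#' stage 2 keeps the `"species-specific"` label.
#'
#' @param candidates named character vector of query protein sequences.
#' @param anchors1,anchors2 lists with elements `seqs` (named character
#'   vector) and `labels` (named character vector tip -> group); the two
#'   anchor sets must be disjoint.
#' @param n_boot bootstrap replicates per stage (default 100, scaled down
#'   from the customary 1000; configurable).
#' @param seed integer seed.
#' @param ... further arguments passed to [assign_groups()].
#' @return object of class `myb_groups`: data frame `assignments` (query,
#'   stage, group, support, nearest_anchor, nearest_distance), plus
#'   `trees` (stage-1/2 trees) and `counts` (stage totals).
#' @export
two_stage_classify <- function(candidates, anchors1, anchors2,
                               n_boot = 100L, seed = 1L, ...) {
  stopifnot(is.character(candidates), length(candidates) > 0)
  if (length(intersect(names(anchors1$seqs), names(anchors2$seqs)))) {
    stop("anchor sets must be disjoint")
  }
  run_stage <- function(queries, anchors, stage) {
    aln <- progressive_msa(c(queries, anchors$seqs))
    bs <- bootstrap_supports(aln, n_reps = n_boot,
                             seed = derive_seed(seed, paste0("stage", stage)))
    asg <- assign_groups(bs$tree, anchors$labels, ...)
    asg$stage <- stage
    list(assignments = asg, tree = bs$tree)
  }
  s1 <- run_stage(candidates, anchors1, 1L)
  unlabeled <- s1$assignments$query[s1$assignments$group ==
                                      "species-specific"]
  labeled1 <- s1$assignments[s1$assignments$group != "species-specific", ,
                             drop = FALSE]
  if (length(unlabeled) >= 1) {
    s2 <- run_stage(candidates[unlabeled], anchors2, 2L)
    assignments <- rbind(labeled1, s2$assignments)
    trees <- list(stage1 = s1$tree, stage2 = s2$tree)
  } else {
    assignments <- labeled1
    trees <- list(stage1 = s1$tree, stage2 = NULL)
  }
  assignments <- assignments[match(names(candidates), assignments$query), ,
                             drop = FALSE]
  rownames(assignments) <- NULL
  structure(list(assignments = assignments, trees = trees,
                 counts = c(total = length(candidates),
                            stage1_labeled = nrow(labeled1),
                            stage2_input = length(unlabeled))),
            class = "myb_groups")
}

#' @export
print.myb_groups <- function(x, ...) {
  cat("Two-stage anchor-guided group classification\n")
  cat(sprintf("  candidates     : %d\n", x$counts[["total"]]))
  cat(sprintf("  stage-1 labels : %d\n", x$counts[["stage1_labeled"]]))
  cat(sprintf("  stage-2 input  : %d\n", x$counts[["stage2_input"]]))
  tab <- sort(table(x$assignments$group), decreasing = TRUE)
  cat("  groups         :",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
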