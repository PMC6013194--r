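test_that("pairwise_align matches an independent DP oracle", {
  expect_error(pairwise_align("A", ""), "non-empty")
  data(BLOSUM62, package = "Biostrings", envir = environment())
  # identical sequences: score is the diagonal sum, no gaps
  res <- pairwise_align("AMKW", "AMKW")
  expect_equal(res$score, sum(diag(BLOSUM62[c("A", "M", "K", "W"),
                                            c("A", "M", "K", "W")])))
  expect_false(grepl("-", paste(res$alignment, collapse = "")))
  # random short toys vs the oracle
  set.seed(14)
  for (i in 1:20) {
    a <- random_peptide(sample(3:12, 1))
    b <- random_peptide(sample(3:12, 1))
    expect_equal(pairwise_align(a, b)$score,
                 nw_score_oracle(a, b, BLOSUM62), tolerance = 1e-9)
  }
})

test_that("progressive_msa preserves obvious alignments", {
  ident <- stats::setNames(rep(strrep("MKVLAW", 10), 3), c("a", "b", "c"))
  aln <- progressive_msa(ident)
  expect_false(any(grepl("-", aln)))
  expect_equal(unname(nchar(aln)), rep(60, 3))

  # disjoint single substitutions: no gaps, width = consensus length
  set.seed(3)
  cons <- random_peptide(60)
  seqs <- vapply(1:5, function(i) {
    ch <- strsplit(cons, "")[[1]]
    ch[i * 10] <- sample(setdiff(AA20, ch[i * 10]), 1)
    paste(ch, collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", 1:5)
  aln <- progressive_msa(seqs)
  expect_false(any(grepl("-", aln)))
  expect_equal(unique(nchar(aln)), 60L)
  # input-order invariance up to row order
  aln_rev <- progressive_msa(rev(seqs))
  expect_equal(aln[names(seqs)], aln_rev[names(seqs)])
  expect_error(progressive_msa(seqs[1]), "at least 2")
})

test_that("p-distance uses pairwise gap deletion", {
  expect_equal(distance_matrix(c(a = "AAAA", b = "AAAA"))["a", "b"], 0)
  expect_equal(distance_matrix(c(a = "AAAA", b = "AAAT"))["a", "b"], 0.25)
  # gapped pair compares only the 3 sites gap-free in both
  D <- distance_matrix(c(a = "A-CA", b = "AGCA"))
  expect_equal(D["a", "b"], 0)
  D2 <- distance_matrix(c(a = "A-CT", b = "AGCA"))
  expect_equal(D2["a", "b"], 1 / 3)
  expect_error(distance_matrix(c(a = "--AA", b = "GG--")),
               "no comparable.*a and b")
})

test_that("nj_tree reproduces the worked additive example", {
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 6
  D["B", "C"] <- 6; D["B", "D"] <- 7; D["C", "D"] <- 7
  D <- D + t(D)
  tr <- nj_tree(D)
  # topology (A,B | C,D) with leaf branches 1,2,3,4 and internal branch 1
  tip_len <- stats::setNames(
    tr$edge.length[match(seq_along(tr$tip.label), tr$edge[, 2])],
    tr$tip.label)
  expect_equal(tip_len[c("A", "B", "C", "D")],
               c(A = 1, B = 2, C = 3, D = 4))
  internal <- tr$edge.length[tr$edge[, 2] > length(tr$tip.label)]
  expect_equal(internal, 1)
  expect_equal(stats::cophenetic(tr)[rownames(D), colnames(D)], D)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("nj_tree round-trips random additive matrices and agrees with ape", {
  set.seed(77)
  for (r in 1:10) {
    D <- random_additive_matrix(sample(4:8, 1))
    tr <- nj_tree(D)
    expect_equal(stats::cophenetic(tr)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
    # independent cross-check: same unrooted topology as ape's NJ
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                           ape::unroot(ape::nj(D)))), 0)
  }
})

test_that("bootstrap supports behave like bipartition frequencies", {
  # every column supports AB|CD
  aln <- c(a = strrep("A", 10), b = strrep("A", 10),
           c = strrep("T", 10), d = strrep("T", 10))
  aln <- stats::setNames(paste0(aln, c("C", "G", "C", "G")),
                         names(aln))
  bs <- bootstrap_supports(aln, n_reps = 50, seed = 1)
  expect_true(all(bs$supports >= 0 & bs$supports <= 100))
  internal_edge <- bs$supports[length(bs$supports)]
  expect_equal(unname(internal_edge), 100)
  # a single replicate gives supports in {0, 100}
  bs1 <- bootstrap_supports(aln, n_reps = 1, seed = 2)
  expect_true(all(bs1$supports %in% c(0, 100)))
  expect_error(bootstrap_supports(c(a = "", b = ""), n_reps = 1), "width")
})

test_that("conflicting-signal bootstrap matches the binomial expectation", {
  # width 12: six columns support AB|CD, six support AC|BD
  colAB <- c(a = "A", b = "A", c = "T", d = "T")
  colAC <- c(a = "A", b = "T", c = "A", d = "T")
  aln <- vapply(c("a", "b", "c", "d"), function(s)
    paste(c(rep(colAB[s], 6), rep(colAC[s], 6)), collapse = ""),
    character(1))
  n_reps <- 1000
  bs <- bootstrap_supports(aln, n_reps = n_reps, seed = 5)
  # exact enumeration: a replicate supports AB|CD iff it draws more AB
  # columns than AC columns; at a 6-6 draw the deterministic label-sorted
  # tie-break in nj_tree always joins (a, b) first
  k <- 0:12
  p_ab <- sum(stats::dbinom(k[k > 6], 12, 0.5)) +
    stats::dbinom(6, 12, 0.5)
  # the non-trivial internal edge has the smaller support (the root
  # "bipartition" is present in every replicate)
  support_ab <- min(bs$supports)
  expect_lt(abs(support_ab - 100 * p_ab), 5)
})

test_that("anchored group assignment follows clade majorities", {
  # build a tree by hand: two anchored clades and one distant query
  nwk <- paste0("((q1:0.05,(anc1:0.05,anc2:0.05):0.02):0.3,",
                "(q2:0.05,(anc3:0.05,anc4:0.05):0.02):0.3,",
                "qfar:3.0);")
  tr <- ape::read.tree(text = nwk)
  anchors <- c(anc1 = "C9", anc2 = "C9", anc3 = "C2", anc4 = "C2")
  asg <- assign_groups(tr, anchors)
  res <- stats::setNames(asg$group, asg$query)
  expect_equal(res[["q1"]], "C9")
  expect_equal(res[["q2"]], "C2")
  expect_equal(res[["qfar"]], "species-specific")
  expect_error(assign_groups(tr, c(zzz = "C1")), "no anchor")
  # total function: every query receives exactly one label
  expect_setequal(asg$query, c("q1", "q2", "qfar"))
})

test_that("two-stage classification recovers anchor-seeded groups", {
  bench <- classification_benchmark(divergence = 0, seed = 17,
                                    members_per_group = 2L)
  res <- two_stage_classify(bench$candidates, bench$anchors1,
                            bench$anchors2, n_boot = 10, seed = 17)
  truth <- bench$truth[!bench$truth$is_anchor, ]
  got <- res$assignments$group[match(truth$id, res$assignments$query)]
  expect_equal(mean(got == truth$group), 1)
  expect_equal(unname(res$counts["stage2_input"]),
               unname(res$counts["total"] - res$counts["stage1_labeled"]))
  # reruns with the same seed are identical
  res2 <- two_stage_classify(bench$candidates, bench$anchors1,
                             bench$anchors2, n_boot = 10, seed = 17)
  expect_identical(res$assignments, res2$assignments)
})
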