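test_that("all_vs_all normalizes by self-scores and matches a DP oracle", {
  s <- c(x = "MKVLAWCQ", y = "MKVLAWCQ")
  e <- all_vs_all(s, s, min_score = 1)
  expect_equal(nrow(e), 1)
  expect_equal(e$weight, 1.0)   # identical sequences
  expect_error(all_vs_all(character(0), s), "non-empty")

  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(70)
  for (i in 1:15) {
    a <- stats::setNames(random_peptide(sample(4:12, 1)), "a")
    b <- stats::setNames(random_peptide(sample(4:12, 1)), "b")
    e <- all_vs_all(a, b, min_score = -Inf)
    expect_equal(e$score, sw_score_oracle(a[[1]], b[[1]], BLOSUM62),
                 tolerance = 1e-9)
  }

  # unrelated random sequences with the auto threshold: no cross edges
  set.seed(71)
  A <- stats::setNames(vapply(1:6, function(i) random_peptide(120),
                              character(1)), paste0("a", 1:6))
  B <- stats::setNames(vapply(1:6, function(i) random_peptide(120),
                              character(1)), paste0("b", 1:6))
  expect_equal(nrow(all_vs_all(A, B, seed = 71)), 0)
})

test_that("rbh keeps only unique mutual best partners", {
  e <- data.frame(idA = c("a1", "a1", "a2", "a2"),
                  idB = c("b1", "b2", "b1", "b2"),
                  weight = c(0.9, 0.2, 0.3, 0.8))
  pairs <- rbh(e)
  expect_equal(nrow(pairs), 2)
  expect_setequal(paste(pairs$idA, pairs$idB), c("a1 b1", "a2 b2"))
  # a1's best is b1 but b1's best is a2: no pair for a1
  e2 <- data.frame(idA = c("a1", "a2"), idB = c("b1", "b1"),
                   weight = c(0.5, 0.9))
  expect_equal(nrow(rbh(e2)), 1)
  expect_equal(rbh(e2)$idA, "a2")
  # exact ties are excluded
  e3 <- data.frame(idA = c("a1", "a1"), idB = c("b1", "b2"),
                   weight = c(0.7, 0.7))
  expect_equal(nrow(rbh(e3)), 0)
  # symmetry in A/B arguments
  swapped <- data.frame(idA = e$idB, idB = e$idA, weight = e$weight)
  ps <- rbh(swapped)
  expect_setequal(paste(ps$idB, ps$idA), paste(pairs$idA, pairs$idB))
})

test_that("mcl partitions graphs as the iteration dictates", {
  tri <- function(p) {
    data.frame(idA = paste0(p, c("1", "2", "1")),
               idB = paste0(p, c("2", "3", "3")), weight = 1)
  }
  res <- mcl(rbind(tri("x"), tri("y")))
  expect_equal(length(res$clusters), 2)
  expect_equal(sort(unname(vapply(res$clusters, length, integer(1)))),
               c(3L, 3L))
  expect_true(res$converged)
  # single edge: one cluster of both nodes
  res1 <- mcl(data.frame(idA = "u", idB = "v", weight = 1))
  expect_equal(length(res1$clusters), 1)
  # partition property and node-order invariance
  expect_equal(sort(unlist(res$clusters, use.names = FALSE)),
               sort(c(paste0("x", 1:3), paste0("y", 1:3))))
  edges <- rbind(tri("x"), tri("y"))
  resr <- mcl(edges[sample(nrow(edges)), ])
  norm_part <- function(r) unname(lapply(
    r$clusters[order(vapply(r$clusters, min, character(1)))], sort))
  expect_equal(norm_part(res), norm_part(resr))
})

test_that("weak bridges are cut at inflation 2 (independent iteration oracle)", {
  clique <- function(p, w = 1) {
    n <- paste0(p, 1:4)
    cmb <- utils::combn(n, 2)
    data.frame(idA = cmb[1, ], idB = cmb[2, ], weight = w)
  }
  edges <- rbind(clique("x"), clique("y"),
                 data.frame(idA = "x1", idB = "y1", weight = 0.05))
  res <- mcl(edges, inflation = 2)
  expect_equal(length(res$clusters), 2)
  # independent oracle: run the stated iteration with plain loops
  nodes <- sort(unique(c(edges$idA, edges$idB)))
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    A[edges$idA[i], edges$idB[i]] <- edges$weight[i]
    A[edges$idB[i], edges$idA[i]] <- edges$weight[i]
  }
  diag(A) <- 1
  M <- sweep(A, 2, colSums(A), "/")
  for (it in 1:200) {
    M <- M %*% M
    M <- M ^ 2
    M[M < 1e-5] <- 0
    M <- sweep(M, 2, pmax(colSums(M), 1e-300), "/")
  }
  supp <- (M > 0) | t(M > 0)
  # oracle components via repeated boolean closure
  reach <- supp
  for (k in seq_len(nrow(supp))) reach <- reach | (reach %*% supp > 0)
  comp <- apply(reach, 1, function(r) paste(sort(nodes[r]), collapse = ","))
  expect_equal(length(unique(comp)), 2)
  oracle_parts <- sort(unique(comp))
  got_parts <- sort(unname(vapply(res$clusters, function(cl)
    paste(sort(cl), collapse = ","), character(1))))
  expect_equal(got_parts, oracle_parts)
})

test_that("call_pairs recovers planted duplication structure", {
  # family 1: A duplicated (a1, a2), one B ortholog closest to a1
  # family 2: single A and B copies
  set.seed(73)
  f1 <- random_peptide(100)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(seq_along(ch), k)
    ch[i] <- vapply(ch[i], function(a) sample(setdiff(AA20, a), 1), "")
    paste(ch, collapse = "")
  }
  a1 <- f1; a2 <- mut(f1, 4); b1 <- mut(f1, 10)
  f2 <- random_peptide(100)
  a3 <- f2; b2 <- mut(f2, 3)
  A <- c(a1 = a1, a2 = a2, a3 = a3)
  B <- c(b1 = b1, b2 = b2)
  cross <- all_vs_all(A, B, min_score = 100)
  withinA <- all_vs_all(A, A, min_score = 100)
  edges <- rbind(cross, withinA)
  pairs <- rbh(cross)
  cl <- mcl(edges)
  called <- call_pairs(cl, edges, pairs,
                       species = c(a1 = "A", a2 = "A", a3 = "A",
                                   b1 = "B", b2 = "B"))
  expect_setequal(paste(called$orthologs$idA, called$orthologs$idB),
                  c("a1 b1", "a3 b2"))
  expect_equal(nrow(called$orthologs), nrow(pairs))  # <= RBH count
  # the duplicated pair is called paralogous
  expect_true(any((called$paralogs$idA == "a1" &
                     called$paralogs$idB == "a2") |
                    (called$paralogs$idA == "a2" &
                       called$paralogs$idB == "a1")))
  expect_true(all(called$paralogs$species == "A"))
})
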