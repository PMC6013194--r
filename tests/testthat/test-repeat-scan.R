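test_that("build_profile matches the log-odds formula", {
  # column identical to background: every score is exactly 0 (any
  # pseudocount), because the smoothed frequency equals the background
  aln <- stats::setNames(vapply(AA20, function(a) strrep(a, 12),
                                character(1)), paste0("s", 1:20))
  prof <- build_profile(aln, pseudocount = 1)
  expect_equal(max(abs(prof$log_odds)), 0, tolerance = 1e-12)

  # 3-sequence toy, pseudocount 1: direct formula evaluation
  toy <- c(a = "ARNDARNDARND", b = "ARNDARNDARND", c = "AANDARNDARND")
  prof <- build_profile(toy, pseudocount = 1)
  bg <- 1 / 20
  expect_equal(unname(prof$log_odds[1, "A"]),
               log2(((3 + 1 * bg) / (3 + 1)) / bg))
  expect_equal(unname(prof$log_odds[2, "R"]),
               log2(((2 + 1 * bg) / (3 + 1)) / bg))
  expect_equal(unname(prof$log_odds[2, "A"]),
               log2(((1 + 1 * bg) / (3 + 1)) / bg))
  expect_equal(unname(prof$log_odds[2, "W"]),
               log2(((0 + 1 * bg) / (3 + 1)) / bg))

  # small-pseudocount limit: consensus -> log2(1/bg), others very negative
  ident <- c(a = strrep("W", 12), b = strrep("W", 12))
  prof <- build_profile(ident, pseudocount = 1e-9)
  expect_equal(unname(prof$log_odds[1, "W"]), log2(20), tolerance = 1e-6)
  expect_lt(prof$log_odds[1, "A"], -20)

  # gap handling and error contracts
  expect_error(build_profile(c(a = "AAA", b = "AAAA")), "ragged")
  expect_error(build_profile(c(a = "AAAA")), "at least 2")
  gappy <- c(a = paste0(strrep("A", 11), "-"),
             b = paste0(strrep("A", 11), "-"),
             c = paste0(strrep("A", 11), "C"))
  expect_equal(build_profile(gappy)$width, 11)  # >50% gap column dropped
})

test_that("scan_repeats finds planted repeats at exact coordinates", {
  set.seed(42)
  cons <- DEFAULT_REPEAT_CONSENSUS
  W <- nchar(cons)
  prof <- build_profile(generate_seed_alignment(cons, seed = 2))
  thr <- calibrate_thresholds(prof, seed = 2)
  bg <- random_peptide(300)
  protein <- paste0(substr(bg, 1, 99), cons, substr(bg, 100 + W, 300))
  hits <- scan_repeats(protein, prof, thr)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 100)
  expect_equal(hits$end, 100 + W - 1)
  expect_equal(hits$completeness, 1)
  # a protein shorter than the minimal partial width gives no hits
  expect_equal(nrow(scan_repeats("MKV", prof, thr)), 0)
})

test_that("greedy overlap resolution matches the exhaustive oracle", {
  # independent oracle: rescore all full-width windows with plain loops,
  # then maximize total score over non-overlapping subsets by recursion
  set.seed(8)
  cons <- DEFAULT_REPEAT_CONSENSUS
  W <- nchar(cons)
  prof <- build_profile(generate_seed_alignment(cons, seed = 8))
  thr <- calibrate_thresholds(prof, seed = 8)
  # two planted repeats overlapping by 20 residues cannot both be kept
  mut <- function(s) {
    ch <- strsplit(s, "")[[1]]
    i <- sample(seq_along(ch), 3)
    ch[i] <- vapply(ch[i], function(a) sample(setdiff(AA20, a), 1), "")
    paste(ch, collapse = "")
  }
  protein <- paste0(random_peptide(30), mut(cons), random_peptide(180))
  protein <- paste0(substr(protein, 1, 40), mut(cons),
                    substr(protein, 41 + W, nchar(protein)))
  window_scores <- function(protein) {
    ch <- strsplit(protein, "")[[1]]
    L <- length(ch)
    vapply(seq_len(L - W + 1), function(i) {
      sum(vapply(seq_len(W), function(j)
        prof$log_odds[j, ch[i + j - 1]], numeric(1)))
    }, numeric(1))
  }
  sc <- window_scores(protein)
  cand <- which(sc >= thr$min_score)
  best_subset_score <- function(cand, sc) {
    if (!length(cand)) return(0)
    rec <- function(k) {
      if (k > length(cand)) return(0)
      skip <- rec(k + 1)
      nxt <- which(cand > cand[k] + W - 1)
      nxt <- nxt[nxt > k]
      take <- sc[cand[k]] + if (length(nxt)) rec(min(nxt)) else 0
      max(skip, take)
    }
    rec(1)
  }
  oracle <- best_subset_score(cand, sc)
  hits <- scan_repeats(protein, prof,
                       list(min_score = thr$min_score,
                            partial = 1e9, min_completeness = 0.4))
  expect_equal(sum(hits$score), oracle, tolerance = 1e-9)
})

test_that("random background yields no hits and thresholds are monotone", {
  set.seed(19)
  prof <- build_profile(generate_seed_alignment(seed = 19))
  thr <- calibrate_thresholds(prof, seed = 19)
  for (i in 1:10) {
    expect_equal(nrow(scan_repeats(random_peptide(400), prof, thr)), 0)
  }
  # raising min_score never increases the hit count
  sp <- family_spec(c(R2R3 = 5), seed = 19)
  pr <- generate_proteome(sp)
  for (id in names(pr$proteins)) {
    h1 <- nrow(scan_repeats(pr$proteins[[id]], prof, thr))
    thr2 <- thr
    thr2$min_score <- thr$min_score + 50
    thr2$partial <- thr$partial + 50
    h2 <- nrow(scan_repeats(pr$proteins[[id]], prof, thr2))
    expect_lte(h2, h1)
  }
})

test_that("classify_architecture applies the repeat-count rules", {
  hit <- function(start, end, completeness = 1)
    data.frame(start = start, end = end, score = 100,
               completeness = completeness)
  two <- rbind(hit(1, 52), hit(58, 109))          # gap 5
  expect_equal(classify_architecture(two)$subfamily, "R2R3")
  three <- rbind(hit(1, 52), hit(58, 109), hit(115, 166))
  expect_equal(classify_architecture(three)$subfamily, "R1R2R3")
  one <- hit(10, 61)
  expect_equal(classify_architecture(one)$subfamily, "MYB_RELATED")
  partial <- hit(10, 35, completeness = 0.5)
  expect_equal(classify_architecture(partial)$subfamily, "ATYPICAL")
  none <- data.frame(start = integer(0), end = integer(0),
                     score = numeric(0), completeness = numeric(0))
  expect_equal(classify_architecture(none)$subfamily, "NOT_MYB")
  # distant repeats do not form one architecture: max adjacent run wins
  distant <- rbind(hit(1, 52), hit(200, 251))
  expect_equal(classify_architecture(distant,
                                     max_adjacent_gap = 30)$subfamily,
               "MYB_RELATED")
  expect_equal(classify_architecture(distant)$n_adjacent, 1)
  five <- rbind(hit(1, 52), hit(55, 106), hit(110, 161), hit(165, 216),
                hit(220, 271))
  cls <- classify_architecture(five)
  expect_equal(cls$subfamily, "FOUR_R")
  expect_true(cls$flag_gt4)
})

test_that("census recovers planted class counts at zero noise", {
  sp <- family_spec(c(MYB_RELATED = 5, R2R3 = 10, R1R2R3 = 2, FOUR_R = 1,
                      ATYPICAL = 3, NOT_MYB = 20),
                    substitution_rate = 0, seed = 23)
  pr <- generate_proteome(sp)
  prof <- build_profile(generate_seed_alignment(seed = 23))
  cz <- census(pr$proteins, prof, seed = 23)
  expect_equal(unname(cz$counts[c("MYB_RELATED", "R2R3", "R1R2R3",
                                  "FOUR_R", "ATYPICAL")]),
               c(5, 10, 2, 1, 3))
  expect_equal(cz$total, 21)
  expect_equal(sum(cz$counts), sum(cz$architectures$subfamily != "NOT_MYB"))
  # record-order invariance
  cz2 <- census(rev(pr$proteins), prof, seed = 23)
  a1 <- cz$architectures[order(cz$architectures$id), ]
  a2 <- cz2$architectures[order(cz2$architectures$id), ]
  rownames(a1) <- rownames(a2) <- NULL
  expect_equal(a1, a2)
})

test_that("representative_per_gene keeps the longest isoform", {
  seqs <- c("g1.1" = "MKVLA", "g1.2" = "MKVLAWWW", "g2.1" = "MK")
  rep <- representative_per_gene(seqs)
  expect_equal(unname(rep), c("MKVLAWWW", "MK"))
  expect_equal(names(rep), c("g1.2", "g2.1"))
})
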