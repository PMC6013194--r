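test_that("generate_repeat respects the substitution model", {
  cons <- strrep("W", 52)
  set.seed(1)
  expect_identical(generate_repeat(cons, 0), cons)
  set.seed(1)
  mutated <- generate_repeat(cons, 1)
  expect_false(any(strsplit(mutated, "")[[1]] ==
                     strsplit(cons, "")[[1]]))
  expect_error(generate_repeat("", 0.1), "non-empty")
  expect_error(generate_repeat("WWW", 1.5), "\\[0,1\\]")
  # binomial sampling check: 10,000 positions at rate 0.1
  set.seed(7)
  long <- paste(rep("A", 10000), collapse = "")
  obs <- 1 - mean(strsplit(generate_repeat(long, 0.1), "")[[1]] == "A")
  sd3 <- 3 * sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(obs - 0.1), sd3)
})

test_that("generate_proteome plants architectures with exact ground truth", {
  sp <- family_spec(c(R2R3 = 3), substitution_rate = 0, seed = 11)
  pr <- generate_proteome(sp)
  expect_length(pr$proteins, 3)
  reps <- pr$truth$repeats
  expect_equal(nrow(reps), 6)   # 2 repeats per protein
  for (i in seq_len(nrow(reps))) {
    seq <- pr$proteins[[reps$id[i]]]
    expect_identical(substr(seq, reps$start[i], reps$end[i]),
                     sp$repeat_consensus)
  }
  # class tallies equal the requested counts
  sp2 <- family_spec(c(MYB_RELATED = 4, R2R3 = 5, R1R2R3 = 2, FOUR_R = 1,
                       ATYPICAL = 3, NOT_MYB = 6), seed = 3)
  pr2 <- generate_proteome(sp2)
  tab <- table(pr2$truth$proteins$class)
  expect_equal(as.integer(tab[c("MYB_RELATED", "R2R3", "R1R2R3", "FOUR_R",
                                "ATYPICAL", "NOT_MYB")]),
               c(4, 5, 2, 1, 3, 6))
  # back-translation with stop codon
  expect_true(all(nchar(pr2$cds) == 3 * nchar(pr2$proteins) + 3))
  # atypical partial covers 40-60% of the consensus
  at <- pr2$truth$repeats[!pr2$truth$repeats$complete, , drop = FALSE]
  frac <- (at$end - at$start + 1) / nchar(sp2$repeat_consensus)
  expect_true(all(frac >= 0.38 & frac <= 0.62))
})

test_that("generation is byte-identical under the same seed", {
  sp <- family_spec(c(R2R3 = 4, NOT_MYB = 4), seed = 99)
  expect_identical(generate_proteome(sp), generate_proteome(sp))
  pr <- generate_proteome(sp)
  g1 <- generate_gene_models(sp, pr)
  g2 <- generate_gene_models(sp, pr)
  expect_identical(g1, g2)
})

test_that("impossible repeat geometry is a generation error", {
  sp <- family_spec(c(FOUR_R = 1), background_length = c(60, 100),
                    inter_repeat_gap = c(5, 10), seed = 1)
  expect_error(generate_proteome(sp), "impossible geometry")
})

test_that("gene models are hierarchy-valid with consistent exon spans", {
  sp <- family_spec(c(R2R3 = 6, MYB_RELATED = 4), seed = 21)
  pr <- generate_proteome(sp)
  gm <- generate_gene_models(sp, pr, exons_per_gene = 3L)
  path <- tempfile(fileext = ".gff3")
  writeLines(gm$gff_lines, path)
  models <- parse_gff3(path)
  expect_setequal(models$genes$gene, names(pr$proteins))
  for (g in models$genes$gene) {
    st <- exon_intron_structure(
      models$exons[models$exons$gene == g, , drop = FALSE])
    expect_equal(st$n_introns, st$n_exons - 1L)   # introns = exons - 1
    expect_equal(st$n_exons, 3L)
    # exon spans sum to CDS length
    expect_equal(sum(st$exon_lengths), nchar(pr$cds[[g]]))
  }
  # placements within chromosome bounds; tallies conserved
  expect_true(all(gm$models$start >= 1))
  expect_true(all(gm$models$end <= sp$chromosome_length))
  expect_equal(sum(table(gm$models$chromosome)), nrow(gm$models))
  # strands recovered exactly through the GFF3 round trip
  expect_equal(models$genes$strand[match(gm$models$gene,
                                         models$genes$gene)],
               gm$models$strand)
})

test_that("qPCR generator inverts the 2^-ddCt model", {
  fc <- data.frame(gene = rep(c("g1", "g2"), each = 3),
                   cultivar = "ZX", stage_DAFB = rep(c(51, 64, 75), 2),
                   fold = c(1, 4, 0.25, 1, 1, 1))
  ct <- generate_qpcr_table(fc, ct_noise_sd = 0, seed = 5)
  res <- ddct_fold(delta_ct(ct, "RPII"))
  res <- res[res$gene != "RPII", ]
  merged <- merge(res, fc, by = c("gene", "cultivar", "stage_DAFB"))
  expect_equal(merged$fold.x, merged$fold.y, tolerance = 1e-12)
  # all-fold-1 at zero noise: every ddct is 0
  expect_true(all(abs(res$ddct[res$gene == "g2"]) < 1e-12))
  expect_error(generate_qpcr_table(transform(fc, fold = -fold)),
               "positive")
  expect_error(
    generate_qpcr_table(data.frame(gene = "g", cultivar = "ZX",
                                   stage_DAFB = c(51, 64),
                                   fold = c(2, 1))),
    "calibrator")
})

test_that("noisy qPCR recovery error matches the propagated bound", {
  sigma <- 0.2
  genes <- sprintf("g%02d", 1:50)
  set.seed(31)
  fc <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene = g, cultivar = "ZX",
               stage_DAFB = c(51, 64, 75, 84, 93),
               fold = c(1, 2 ^ stats::runif(4, -3, 3)))
  }))
  ct <- generate_qpcr_table(fc, ct_noise_sd = sigma, seed = 13)
  res <- ddct_fold(delta_ct(ct, "RPII"))
  res <- res[res$gene != "RPII" & !res$is_calibrator, ]
  merged <- merge(res, fc, by = c("gene", "cultivar", "stage_DAFB"))
  err <- abs(log2(merged$fold.x) - log2(merged$fold.y))
  expect_gte(nrow(merged), 200)
  expect_lt(mean(err), 3 * sigma * sqrt(2 / 3))
})
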