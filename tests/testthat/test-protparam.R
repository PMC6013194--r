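test_that("molecular weight follows the average-mass table", {
  expect_equal(molecular_weight("G"), 75.067, tolerance = 1e-3)
  expect_equal(molecular_weight("AG"), 146.146, tolerance = 1e-3)
  # additivity: MW(s + X) = MW(s) + residue mass of X
  set.seed(81)
  for (i in 1:10) {
    s <- random_peptide(sample(5:40, 1))
    x <- sample(AA20, 1)
    expect_equal(molecular_weight(paste0(s, x)) - molecular_weight(s),
                 molecular_weight(x) - (75.067 - 57.0519),
                 tolerance = 1e-3)
  }
  expect_error(molecular_weight("AXG"), "non-standard")
  expect_warning(mw <- molecular_weight("AXG", tolerate_nonstandard = TRUE),
                 "skipping")
  expect_equal(mw, molecular_weight("AG"))
})

test_that("pI solves the charge balance; termini midpoint is closed form", {
  # no ionizable side chains with the EMBOSS-style termini: the closed-form
  # midpoint (8.6 + 3.6) / 2 = 6.1
  expect_equal(isoelectric_point("AAAA", pka = "emboss"), 6.1,
               tolerance = 0.02)
  # monotone composition effects
  base <- "AAGAGA"
  expect_gt(isoelectric_point(paste0(base, "K")),
            isoelectric_point(base))
  expect_lt(isoelectric_point(paste0(base, "D")),
            isoelectric_point(base))
  expect_error(isoelectric_point(""), "non-standard|empty")
})

test_that("GRAVY is the mean Kyte-Doolittle value with table bounds", {
  expect_equal(gravy("KKK"), -3.9)
  expect_equal(gravy("AV"), 3.0)
  set.seed(82)
  for (i in 1:20) {
    g <- gravy(random_peptide(sample(2:100, 1)))
    expect_gte(g, -4.5); expect_lte(g, 4.5)
  }
})

test_that("instability index matches the dipeptide formula", {
  ii2 <- instability_index("MH")
  expect_equal(ii2$index, 5 * 58.28)   # DIWV(M,H) = 58.28
  expect_true(ii2$unstable)
  # homopolymer: II = 10 (L-1)/L * DIWV(x, x)
  for (L in c(2, 5, 50)) {
    ii <- instability_index(strrep("P", L))
    expect_equal(ii$index, 10 * (L - 1) / L * 20.26, tolerance = 1e-9)
  }
  expect_error(instability_index("A"), "at least 2")
})

test_that("all four measures agree with independent recomputation", {
  # independent oracle: plain-loop summation over the published tables as
  # shipped, plus a brute bisection for pI
  masses <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, Q = 128.1307, E = 129.1155, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  charge_expasy <- function(chars, pH) {
    nt <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
            E = 7.7)
    ct <- c(D = 4.55, E = 4.75)
    posk <- c(K = 10.0, R = 12.0, H = 5.98)
    negk <- c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
    nterm <- if (chars[1] %in% names(nt)) nt[[chars[1]]] else 7.5
    cterm <- if (chars[length(chars)] %in% names(ct))
      ct[[chars[length(chars)]]] else 3.55
    q <- 1 / (1 + 10 ^ (pH - nterm)) - 1 / (1 + 10 ^ (cterm - pH))
    for (a in names(posk)) q <- q + sum(chars == a) /
        (1 + 10 ^ (pH - posk[[a]]))
    for (a in names(negk)) q <- q - sum(chars == a) /
        (1 + 10 ^ (negk[[a]] - pH))
    q
  }
  set.seed(83)
  n_checked <- 0
  for (i in 1:100) {
    s <- random_peptide(sample(10:80, 1))
    ch <- strsplit(s, "")[[1]]
    expect_equal(molecular_weight(s), sum(masses[ch]) + 18.01524,
                 tolerance = 1e-6)
    expect_equal(gravy(s), mean(kd[ch]), tolerance = 1e-6)
    ii_oracle <- 0
    for (k in seq_len(length(ch) - 1)) {
      ii_oracle <- ii_oracle + mybcensus::DIWV[ch[k], ch[k + 1]]
    }
    expect_equal(instability_index(s)$index,
                 10 / length(ch) * ii_oracle, tolerance = 1e-6)
    pi_hat <- isoelectric_point(s)
    expect_lt(abs(charge_expasy(ch, pi_hat)), 1e-4)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 100)
})

test_that("permutation invariance holds for all measures except II", {
  set.seed(84)
  s <- random_peptide(40)
  perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(molecular_weight(s), molecular_weight(perm))
  expect_equal(gravy(s), gravy(perm))
  # the ExPASy set has residue-specific terminal pKas, so permutation
  # invariance of pI holds for the terminal-independent EMBOSS set
  expect_equal(isoelectric_point(s, pka = "emboss"),
               isoelectric_point(perm, pka = "emboss"), tolerance = 1e-6)
  # II depends on dipeptide order: exhibit a differing pair
  expect_false(isTRUE(all.equal(instability_index("MHS")$index,
                                instability_index("HMS")$index)))
})

test_that("batch profile summarizes exactly", {
  set.seed(85)
  seqs <- stats::setNames(vapply(1:5, function(i) random_peptide(30),
                                 character(1)), paste0("p", 1:5))
  pp <- protparam_profile(seqs)
  expect_equal(nrow(pp$profile), 5)
  expect_equal(pp$summary$mw[["mean"]], mean(pp$profile$mw))
  expect_equal(pp$summary$gravy[["min"]], min(pp$profile$gravy))
  expect_equal(pp$profile$unstable, pp$profile$instability > 40)
})
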