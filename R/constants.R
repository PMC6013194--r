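# Shared constant tables: amino-acid alphabet, published physicochemical
# tables (ExPASy average masses, Kyte-Doolittle hydropathy, Guruprasad DIWV
# dipeptide weights, EMBOSS and Bjellqvist pKa sets) and a fixed
# back-translation codon table.

#' Standard amino-acid alphabet used throughout the package
#' @keywords internal
AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Average (not monoisotopic) residue masses in Da (ProtParam convention)
#' @export
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

WATER_MASS <- 18.01524

#' Kyte-Doolittle hydropathy values (bounds -4.5 .. 4.5)
#' @export
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Guruprasad dipeptide instability weight values (DIWV); rows = first
# residue, columns = second residue; default weight 1.0.
.make_diwv <- function() {
  m <- matrix(1.0, 20, 20, dimnames = list(AA_ALPHABET20, AA_ALPHABET20))
  set <- function(a, ...) {
    v <- c(...)
    m[a, names(v)] <<- v
  }
  set("A", C = 44.94, D = -7.49, H = -7.49, P = 20.26)
  set("C", D = 20.26, H = 33.60, L = 20.26, M = 33.60, P = 20.26,
      Q = -6.54, T = 33.60, V = -6.54, W = 24.68)
  set("D", F = -6.54, K = -7.49, R = -6.54, S = 20.26, T = -14.03)
  set("E", C = 44.94, D = 20.26, E = 33.60, H = -6.54, I = 20.26,
      P = 20.26, Q = 20.26, S = 20.26, W = -14.03)
  set("F", D = 13.34, K = -14.03, P = 20.26, Y = 33.601)
  set("G", A = -7.49, E = -6.54, G = 13.34, I = -7.49, K = -7.49,
      N = -7.49, T = -7.49, W = 13.34, Y = -7.49)
  set("H", F = -9.37, G = -9.37, I = 44.94, K = 24.68, N = 24.68,
      P = -1.88, T = -6.54, W = -1.88, Y = 44.94)
  set("I", E = 44.94, H = 13.34, K = -7.49, L = 20.26, P = -1.88, V = -7.49)
  set("K", G = -7.49, I = -7.49, L = -7.49, M = 33.60, P = -6.54,
      Q = 24.64, R = 33.60, V = -7.49)
  set("L", K = -7.49, P = 20.26, Q = 33.60, R = 20.26, W = 24.68)
  set("M", A = 13.34, H = 58.28, M = -1.88, P = 44.94, Q = -6.54,
      R = -6.54, S = 44.94, T = -1.88, Y = 24.68)
  set("N", C = -1.88, F = -14.03, G = -14.03, I = 44.94, K = 24.68,
      P = -1.88, Q = -6.54, T = -7.49, W = -9.37)
  set("P", A = 20.26, C = -6.54, D = -6.54, E = 18.38, F = 20.26,
      M = -6.54, P = 20.26, Q = 20.26, R = -6.54, S = 20.26,
      V = 20.26, W = -1.88)
  set("Q", C = -6.54, D = 20.26, E = 20.26, F = -6.54, P = 20.26,
      Q = 20.26, S = 44.94, V = -6.54, Y = -6.54)
  set("R", G = -7.49, H = 20.26, N = 13.34, P = 20.26, R = 58.28,
      S = 44.94, W = 58.28, Y = -6.54)
  set("S", C = 33.60, E = 20.26, P = 44.94, Q = 20.26, R = 20.26, S = 20.26)
  set("T", E = 20.26, F = 13.34, G = -7.49, N = -14.03, Q = -6.54, W = -14.03)
  set("V", D = -14.03, G = -7.49, K = -1.88, P = 20.26, T = -7.49, Y = -6.54)
  set("W", A = -14.03, G = -9.37, H = 24.68, L = 13.34, M = 24.68,
      N = 13.34, T = -14.03, V = -7.49)
  set("Y", A = 24.68, D = 24.68, E = -6.54, G = -7.49, H = 13.34,
      M = 44.94, P = 13.34, R = -15.91, T = -7.49, W = -9.37, Y = 13.34)
  m
}

#' Guruprasad DIWV dipeptide instability weights (20 x 20)
#' @export
DIWV <- .make_diwv()

# pKa sets for isoelectric-point calculation. The EMBOSS-style set uses one
# pKa per terminus; the Bjellqvist/ExPASy set carries residue-specific
# terminal pKas (the ProtParam convention).
#' EMBOSS-style pKa set for pI calculation
#' @export
PKA_EMBOSS <- list(
  nterm = 8.6, cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1),
  nterm_by_residue = numeric(0), cterm_by_residue = numeric(0))

#' Bjellqvist/ExPASy pKa set with residue-specific termini (default)
#' @export
PKA_EXPASY <- list(
  nterm = 7.5, cterm = 3.55,
  positive = c(K = 10.0, R = 12.0, H = 5.98),
  negative = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0),
  nterm_by_residue = c(A = 7.59, M = 7.0, S = 6.93, P = 8.36,
                       T = 6.82, V = 7.44, E = 7.7),
  cterm_by_residue = c(D = 4.55, E = 4.75))

# Fixed back-translation codon table (first codon per residue); synthetic
# CDS only needs length/frame consistency, not codon-usage realism.
BACKTRANSLATE_CODON <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT")

STOP_CODON <- "TAA"
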