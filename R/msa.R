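# Alignment layer for the phylogenetic stages: global pairwise alignment
# (Biostrings), progressive multiple alignment (mafft), and p-distance
# matrices with pairwise gap deletion, the classic distance model for
# neighbor-joining on protein family alignments.

#' Global pairwise alignment with affine gap penalties
#'
#' @param a,b amino-acid strings.
#' @param substitution_matrix name of a substitution matrix shipped with
#'   Biostrings (default `"BLOSUM62"`), or a matrix.
#' @param gap_open,gap_extend affine gap penalties (costs, ClustalW-like
#'   defaults).
#' @return list with `score` and `alignment` (named character vector of the
#'   two gapped sequences).
#' @export
pairwise_align <- function(a, b, substitution_matrix = "BLOSUM62",
                           gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  list(score = Biostrings::score(pa),
       alignment = c(a = as.character(Biostrings::alignedPattern(pa)),
                     b = as.character(Biostrings::alignedSubject(pa))))
}

#' Progressive multiple sequence alignment
#'
#' Aligns a set of protein sequences with the mafft progressive aligner
#' (FFT-NS-2 style guide tree; deterministic for a given input set). Rows
#' are returned in input order, upper-cased, as a named character vector of
#' equal-length gapped strings.
#'
#' @param seqs named character vector (>= 2 sequences).
#' @param mafft_args extra command-line arguments for mafft.
#' @return named character vector of aligned sequences.
#' @export
progressive_msa <- function(seqs, mafft_args = c("--auto")) {
  if (length(seqs) < 2) stop("need at least 2 sequences to align")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must carry unique names")
  }
  if (Sys.which("mafft") == "") {
    stop("the mafft executable is required for progressive alignment")
  }
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  # safe ids: mafft headers are parsed back positionally
  safe <- sprintf("s%06d", seq_along(seqs))
  write_fasta_vec(stats::setNames(unname(seqs), safe), fin)
  status <- system2("mafft", c("--quiet", mafft_args, fin),
                    stdout = fout, stderr = FALSE)
  if (status != 0) stop("mafft failed with exit status ", status)
  aln <- read_fasta_vec(fout)
  aln <- toupper(aln[safe])
  stats::setNames(aln, names(seqs))
}

#' Pairwise p-distance matrix with pairwise gap deletion
#'
#' `d(i, j)` is the fraction of mismatching sites among the sites where
#' neither sequence has a gap. Pairs with no comparable site are an error
#' (naming the pair), since neighbor-joining cannot use them.
#'
#' @param alignment named character vector of equal-length gapped sequences.
#' @return symmetric numeric matrix with zero diagonal, labelled by
#'   sequence names.
#' @export
distance_matrix <- function(alignment) {
  n <- length(alignment)
  if (n < 2) stop("need at least 2 aligned sequences")
  if (length(unique(nchar(alignment))) != 1) {
    stop("ragged alignment: sequences differ in length")
  }
  mat <- do.call(rbind, strsplit(alignment, ""))
  rownames(mat) <- names(alignment)
  gap <- mat == "-"
  D <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      m <- sum(ok)
      if (m == 0) {
        stop(sprintf("no comparable (gap-free) sites between %s and %s",
                     names(alignment)[i], names(alignment)[j]))
      }
      d <- sum(mat[i, ok] != mat[j, ok]) / m
      D[i, j] <- d; D[j, i] <- d
    }
  }
  D
}
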