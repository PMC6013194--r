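# Seeding and small shared helpers.

#' Derive a reproducible sub-seed for a named generator stream
#'
#' A single user-facing integer seed drives every stochastic component. Each
#' component draws from its own named stream so that adding a new generator
#' never perturbs the draws of existing ones. The stream seed is a
#' deterministic hash of the master seed and the stream name, kept within
#' the 32-bit integer range R requires.
#'
#' @param seed master integer seed.
#' @param stream character stream name (e.g. `"proteome"`, `"qpcr"`).
#' @return an integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(stream)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the RNG to a given seed for the duration of `expr` and restores the
#' caller's RNG state afterwards, so library internals never disturb user
#' simulations.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Split a character vector of sequences into a list of per-residue vectors.
seq_to_chars <- function(x) strsplit(x, "", fixed = TRUE)

# Validate that sequences use only the 20 standard residues.
check_standard_aa <- function(seq, context = "sequence") {
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), AA_ALPHABET20)
  if (length(bad) > 0) {
    stop(sprintf("non-standard residue(s) %s in %s",
                 paste(bad, collapse = ","), context), call. = FALSE)
  }
  invisible(TRUE)
}

# Read/write helpers -------------------------------------------------------

#' Read a protein FASTA into a named character vector
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta_vec <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector of sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta_vec <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  }
  invisible(path)
}

# Consistent numeric formatting for emitted TSVs (keeps manifests stable).
format_num <- function(x, digits = 6) {
  formatC(x, digits = digits, format = "g")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
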