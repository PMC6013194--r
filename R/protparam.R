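# Physicochemical profiling of proteins: average molecular weight,
# theoretical isoelectric point, GRAVY (grand average of hydropathy) and
# the Guruprasad instability index, following the ProtParam conventions
# (average masses, Bjellqvist pKa set with residue-specific termini).

check_or_clean <- function(seq, tolerate_nonstandard, context) {
  chars <- strsplit(seq, "")[[1]]
  bad <- !(chars %in% AA_ALPHABET20)
  if (any(bad)) {
    if (!tolerate_nonstandard) {
      stop(sprintf("non-standard residue(s) %s in %s",
                   paste(unique(chars[bad]), collapse = ","), context))
    }
    warning(sprintf("skipping %d non-standard residue(s) in %s",
                    sum(bad), context))
    chars <- chars[!bad]
  }
  chars
}

#' Average molecular weight of a protein (Da)
#'
#' Sum of average residue masses plus one water mass (18.01524 Da).
#'
#' @param seq amino-acid string.
#' @param tolerate_nonstandard skip non-standard residues with a warning
#'   instead of erroring.
#' @return molecular weight in Daltons.
#' @export
molecular_weight <- function(seq, tolerate_nonstandard = FALSE) {
  chars <- check_or_clean(seq, tolerate_nonstandard, "molecular_weight")
  if (!length(chars)) stop("no standard residues in sequence")
  sum(AA_AVG_MASS[chars]) + WATER_MASS
}

# Net charge at a given pH under the Henderson-Hasselbalch model.
net_charge <- function(chars, pH, pka) {
  first <- chars[1]; last <- chars[length(chars)]
  nterm_pka <- if (first %in% names(pka$nterm_by_residue))
    pka$nterm_by_residue[[first]] else pka$nterm
  cterm_pka <- if (last %in% names(pka$cterm_by_residue))
    pka$cterm_by_residue[[last]] else pka$cterm
  pos <- 1 / (1 + 10 ^ (pH - nterm_pka))
  for (a in names(pka$positive)) {
    n <- sum(chars == a)
    if (n) pos <- pos + n / (1 + 10 ^ (pH - pka$positive[[a]]))
  }
  neg <- 1 / (1 + 10 ^ (cterm_pka - pH))
  for (a in names(pka$negative)) {
    n <- sum(chars == a)
    if (n) neg <- neg + n / (1 + 10 ^ (pka$negative[[a]] - pH))
  }
  pos - neg
}

#' Theoretical isoelectric point
#'
#' Bisection root of the modeled net charge (strictly decreasing in pH) on
#' pH 0-14, to |charge| < 1e-4. Two pKa sets are shipped: the
#' Bjellqvist/ExPASy set with residue-specific terminal pKas (default, the
#' ProtParam convention) and an EMBOSS-style set.
#'
#' @param seq amino-acid string.
#' @param pka `"expasy"`, `"emboss"`, or a pKa list with elements `nterm`,
#'   `cterm`, `positive`, `negative`, `nterm_by_residue`,
#'   `cterm_by_residue`.
#' @param tolerate_nonstandard skip non-standard residues with a warning.
#' @return pI (pH units).
#' @export
isoelectric_point <- function(seq, pka = "expasy",
                              tolerate_nonstandard = FALSE) {
  chars <- check_or_clean(seq, tolerate_nonstandard, "isoelectric_point")
  if (!length(chars)) stop("empty sequence")
  if (is.character(pka)) {
    pka <- switch(match.arg(pka, c("expasy", "emboss")),
                  expasy = PKA_EXPASY, emboss = PKA_EMBOSS)
  }
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(chars, mid, pka)
    if (abs(q) < 1e-4 || (hi - lo) < 1e-10) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of Kyte-Doolittle hydropathy values; bounded by the
#' table extremes -4.5 (Arg) and 4.5 (Ile).
#'
#' @inheritParams molecular_weight
#' @return dimensionless GRAVY value.
#' @export
gravy <- function(seq, tolerate_nonstandard = FALSE) {
  chars <- check_or_clean(seq, tolerate_nonstandard, "gravy")
  if (!length(chars)) stop("empty sequence")
  mean(KYTE_DOOLITTLE[chars])
}

#' Guruprasad instability index
#'
#' `II = (10 / L) * sum of DIWV(x_i, x_i+1)` over the L - 1 dipeptides;
#' a protein with II > 40 is conventionally called unstable.
#'
#' @inheritParams molecular_weight
#' @return list with `index` and `unstable` (logical).
#' @export
instability_index <- function(seq, tolerate_nonstandard = FALSE) {
  chars <- check_or_clean(seq, tolerate_nonstandard, "instability_index")
  L <- length(chars)
  if (L < 2) stop("instability index needs at least 2 residues")
  ii <- 10 / L * sum(DIWV[cbind(chars[-L], chars[-1])])
  list(index = ii, unstable = ii > 40)
}

#' Physicochemical profile of a set of proteins
#'
#' @param seqs named character vector of protein sequences.
#' @param pka pKa set for [isoelectric_point()].
#' @param tolerate_nonstandard skip non-standard residues with a warning.
#' @return object of class `physchem_profile`: data frame `profile` (id,
#'   length, mw, pi, gravy, instability, unstable) plus `summary` (min /
#'   mean / max per measure).
#' @export
protparam_profile <- function(seqs, pka = "expasy",
                              tolerate_nonstandard = FALSE) {
  stopifnot(length(seqs) > 0, !is.null(names(seqs)))
  rows <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    ii <- instability_index(s, tolerate_nonstandard)
    data.frame(id = id, length = nchar(s),
               mw = molecular_weight(s, tolerate_nonstandard),
               pi = isoelectric_point(s, pka, tolerate_nonstandard),
               gravy = gravy(s, tolerate_nonstandard),
               instability = ii$index, unstable = ii$unstable,
               stringsAsFactors = FALSE)
  })
  profile <- do.call(rbind, rows)
  rownames(profile) <- NULL
  summ <- lapply(c(mw = "mw", pi = "pi", gravy = "gravy",
                   instability = "instability"), function(col) {
    c(min = min(profile[[col]]), mean = mean(profile[[col]]),
      max = max(profile[[col]]))
  })
  structure(list(profile = profile, summary = summ, pka = pka),
            class = "physchem_profile")
}

#' @export
print.physchem_profile <- function(x, ...) {
  cat(sprintf("physicochemical profile of %d proteins\n", nrow(x$profile)))
  for (m in names(x$summary)) {
    s <- x$summary[[m]]
    cat(sprintf("  %-12s min %.3f  mean %.3f  max %.3f\n",
                m, s[["min"]], s[["mean"]], s[["max"]]))
  }
  cat(sprintf("  unstable     %d of %d (II > 40)\n",
              sum(x$profile$unstable), nrow(x$profile)))
  invisible(x)
}
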