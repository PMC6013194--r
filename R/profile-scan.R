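# MYB-repeat detection: position-specific scoring matrix (PSSM) built from
# a seed alignment of repeat copies, a sliding-window scanner that also
# scores prefix/suffix sub-profiles for truncated (partial) repeats, and
# the repeat-count rules that classify proteins into subfamilies.
#
# The PSSM is a per-column log-odds profile (no insert/delete states); this
# is the package's deliberate simplification of a full profile HMM and is
# documented as such in the methods vignette.

#' Build a repeat-scanning profile from a seed alignment
#'
#' Columns with more than 50 percent gaps are dropped; remaining columns
#' give per-residue log2 odds against a background distribution, with a
#' Dirichlet-style pseudocount proportional to the background:
#' `log2(((n_ja + pc * bg_a) / (n_j + pc)) / bg_a)` where `n_ja` counts
#' residue a in column j and `n_j` the non-gap residues of column j.
#'
#' @param seed_alignment named character vector of aligned sequences (equal
#'   lengths; `-` for gaps).
#' @param pseudocount positive scalar pseudocount mass.
#' @param background length-20 named frequency vector (sums to 1); default
#'   uniform.
#' @return object of class `repeat_profile` with elements `width`,
#'   `log_odds` (width x 20), `background`, `pseudocount`.
#' @export
build_profile <- function(seed_alignment, pseudocount = 1,
                          background = NULL) {
  if (length(seed_alignment) < 2) {
    stop("need at least 2 aligned sequences")
  }
  lens <- nchar(seed_alignment)
  if (length(unique(lens)) != 1) {
    stop("ragged alignment: sequences differ in length")
  }
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET20)
  }
  background <- background[AA_ALPHABET20]
  if (any(is.na(background)) || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6) {
    stop("background must be a positive frequency vector over the 20 ",
         "standard residues summing to 1")
  }
  mat <- do.call(rbind, strsplit(seed_alignment, ""))
  n_seq <- nrow(mat)
  gap_frac <- colMeans(mat == "-")
  keep <- gap_frac <= 0.5
  if (!any(keep)) stop("all columns exceed the 50% gap threshold")
  mat <- mat[, keep, drop = FALSE]
  width <- ncol(mat)
  if (width < 10) stop("retained profile width must be >= 10 columns")
  log_odds <- matrix(NA_real_, nrow = width, ncol = 20,
                     dimnames = list(NULL, AA_ALPHABET20))
  for (j in seq_len(width)) {
    col <- mat[, j]
    col <- col[col != "-"]
    bad <- setdiff(unique(col), AA_ALPHABET20)
    if (length(bad)) {
      stop("non-standard residue(s) in seed alignment column ", j, ": ",
           paste(bad, collapse = ","))
    }
    counts <- table(factor(col, levels = AA_ALPHABET20))
    freq <- (as.numeric(counts) + pseudocount * background) /
      (length(col) + pseudocount)
    log_odds[j, ] <- unname(log2(freq / background))
  }
  structure(list(width = width, log_odds = log_odds,
                 background = background, pseudocount = pseudocount),
            class = "repeat_profile")
}

#' @export
print.repeat_profile <- function(x, ...) {
  cat(sprintf("MYB repeat scanning profile: %d columns, pseudocount %g\n",
              x$width, x$pseudocount))
  invisible(x)
}

# Encode a protein as profile-column score prefix sums.
# Returns matrix S with S[i, k] = score of profile columns 1..k placed at
# protein position i (NA where the placement exceeds the sequence).
prefix_score_matrix <- function(aa_idx, log_odds) {
  L <- length(aa_idx)
  W <- nrow(log_odds)
  S <- matrix(NA_real_, nrow = L, ncol = W)
  if (L < 1) return(S)
  S[, 1] <- log_odds[1, aa_idx]
  for (k in 2:W) {
    if (k > L) break
    n <- L - k + 1L
    S[seq_len(n), k] <- S[seq_len(n), k - 1L] + log_odds[k, aa_idx[k:L]]
  }
  S
}

#' Calibrate scan thresholds from an empirical null
#'
#' Scores windows of a long random background sequence (drawn from the
#' profile's background frequencies) at every sub-profile width and returns
#' `mean + z * sd` per width. Self-calibrating alternative to a fixed
#' bit-score cutoff, since published family censuses rarely state theirs.
#'
#' @param profile a `repeat_profile`.
#' @param z number of null standard deviations above the null mean.
#' @param null_length length of the null sequence (residues).
#' @param min_completeness minimal sub-profile fraction scored (partial
#'   hits must cover at least this fraction of the profile width).
#' @param floor lower bound (bits) applied to every threshold. The default
#'   0 requires a hit to be more likely under the profile than under the
#'   background (positive log-odds), the usual bit-score convention; the
#'   null term only matters when the empirical null tail rises above it.
#' @param seed integer seed for the null draw.
#' @return list with `min_score` (full width), `partial` (named vector of
#'   thresholds per sub-profile width), `min_completeness`, `z`.
#' @export
calibrate_thresholds <- function(profile, z = 5, null_length = 20000L,
                                 min_completeness = 0.4, floor = 0,
                                 seed = 1L) {
  stopifnot(inherits(profile, "repeat_profile"))
  W <- profile$width
  kmin <- ceiling(min_completeness * W)
  with_seed(derive_seed(seed, "scan_null"), {
    aa_idx <- sample.int(20, null_length, replace = TRUE,
                         prob = profile$background)
    S <- prefix_score_matrix(aa_idx, profile$log_odds)
    ks <- kmin:W
    thr <- vapply(ks, function(k) {
      sc <- S[, k]
      sc <- sc[!is.na(sc)]
      max(mean(sc) + z * stats::sd(sc), floor)
    }, numeric(1))
    names(thr) <- ks
    list(min_score = thr[[as.character(W)]], partial = thr,
         min_completeness = min_completeness, z = z)
  })
}

#' Scan a protein for complete and partial MYB-repeat hits
#'
#' Slides the full-width profile across the protein and additionally scores
#' prefix and suffix sub-profiles (at least `min_completeness` of the
#' profile width) at every position, so truncated repeats are found whether
#' they sit at the termini or internally. Every placement competes at its
#' maximum-likelihood width -- among overlapping candidates the highest bit
#' score wins (greedy, ties by leftmost start) -- so a genuinely truncated
#' repeat beats the full-width window that straddles it plus background,
#' while a full repeat always outscores its own trimmings. Hits whose
#' retained width reaches `complete_min` of the profile count as complete
#' repeats downstream.
#'
#' @param protein amino-acid string.
#' @param profile a `repeat_profile`.
#' @param thresholds result of [calibrate_thresholds()], or a list with
#'   `min_score` (scalar, bits), optional `partial` (scalar or named vector
#'   per width) and `min_completeness`.
#' @param complete_min completeness at or above which a placement counts as
#'   a complete repeat. Each placement keeps its maximum-likelihood width
#'   (highest bit score), so a repeat whose terminal columns are substituted
#'   may be trimmed by a few columns yet still represents the full domain;
#'   0.8 separates such trimmed full repeats from genuinely truncated ones.
#' @return data frame of hits sorted by start: `start`, `end` (1-based
#'   closed), `score` (bits), `completeness` in (0,1].
#' @export
scan_repeats <- function(protein, profile, thresholds, complete_min = 0.8) {
  stopifnot(inherits(profile, "repeat_profile"))
  if (!is.character(protein) || length(protein) != 1 || nchar(protein) < 1) {
    stop("protein must be a non-empty amino-acid string")
  }
  W <- profile$width
  min_comp <- if (!is.null(thresholds$min_completeness))
    thresholds$min_completeness else 0.4
  kmin <- ceiling(min_comp * W)
  empty <- data.frame(start = integer(0), end = integer(0),
                      score = numeric(0), completeness = numeric(0))
  chars <- strsplit(protein, "")[[1]]
  aa_idx <- match(chars, AA_ALPHABET20)
  if (anyNA(aa_idx)) {
    stop("non-standard residue(s) in protein: ",
         paste(unique(chars[is.na(aa_idx)]), collapse = ","))
  }
  L <- length(aa_idx)
  if (L < kmin) return(empty)

  thr_for <- function(k) {
    p <- thresholds$partial
    if (is.null(p)) return(thresholds$min_score)
    if (length(p) == 1 && is.null(names(p))) return(as.numeric(p))
    v <- p[[as.character(k)]]
    if (is.null(v)) thresholds$min_score else v
  }

  S <- prefix_score_matrix(aa_idx, profile$log_odds)
  S_rev <- prefix_score_matrix(rev(aa_idx),
                               profile$log_odds[W:1, , drop = FALSE])
  # complete placements
  complete <- empty
  if (L >= W) {
    sc <- S[, W]
    ok <- which(!is.na(sc) & sc >= thresholds$min_score)
    if (length(ok)) {
      complete <- data.frame(
        start = ok, end = ok + W - 1L, score = sc[ok], completeness = 1)
    }
  }
  # partial placements: profile prefixes (columns 1..k) and suffixes
  # (columns W-k+1..W) at any position
  cand <- list()
  for (k in kmin:(W - 1L)) {
    if (k > L) break
    sc <- S[, k]
    ok <- which(!is.na(sc) & sc >= thr_for(k))
    if (length(ok)) {
      cand[[length(cand) + 1L]] <- data.frame(
        start = ok, end = ok + k - 1L, score = sc[ok], completeness = k / W)
    }
    sc <- S_rev[, k]
    ok <- which(!is.na(sc) & sc >= thr_for(k))
    if (length(ok)) {
      start <- L - ok - k + 2L
      cand[[length(cand) + 1L]] <- data.frame(
        start = start, end = start + k - 1L, score = sc[ok],
        completeness = k / W)
    }
  }
  partial <- if (length(cand)) do.call(rbind, cand) else empty

  greedy <- function(cand, taken_start, taken_end) {
    cand <- cand[order(-cand$score, cand$start, -cand$completeness), ,
                 drop = FALSE]
    keep <- integer(0)
    for (i in seq_len(nrow(cand))) {
      s <- cand$start[i]; e <- cand$end[i]
      if (!any(s <= taken_end & e >= taken_start)) {
        keep <- c(keep, i)
        taken_start <- c(taken_start, s); taken_end <- c(taken_end, e)
      }
    }
    list(hits = cand[keep, , drop = FALSE],
         start = taken_start, end = taken_end)
  }
  out <- greedy(rbind(complete, partial), integer(0), integer(0))$hits
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a protein's repeat architecture into a subfamily
#'
#' Counts the longest run of complete repeat hits whose inter-hit gaps do
#' not exceed `max_adjacent_gap` (repeats must be adjacent to count as one
#' architecture): 1 repeat is MYB-related (1R), 2 is R2R3, 3 is R1R2R3, 4
#' is 4R. A protein with only partial hits is atypical; no hits means not a
#' family member. More than 4 adjacent complete repeats is reported as 4R
#' with a flag.
#'
#' @param hits data frame from [scan_repeats()] (sorted, non-overlapping).
#' @param max_adjacent_gap maximal residue gap between adjacent repeats.
#' @param complete_min completeness at or above which a hit counts as a
#'   complete repeat (see [scan_repeats()]).
#' @return list with `subfamily`, `n_adjacent` (longest adjacent run of
#'   complete hits) and `flag_gt4`.
#' @export
classify_architecture <- function(hits, max_adjacent_gap = 30L,
                                  complete_min = 0.8) {
  comp <- hits[hits$completeness >= complete_min, , drop = FALSE]
  n_part <- sum(hits$completeness < complete_min)
  if (nrow(comp) == 0) {
    sub <- if (n_part > 0) "ATYPICAL" else "NOT_MYB"
    return(list(subfamily = sub, n_adjacent = 0L, flag_gt4 = FALSE))
  }
  comp <- comp[order(comp$start), , drop = FALSE]
  run <- 1L; best <- 1L
  if (nrow(comp) > 1) {
    for (i in 2:nrow(comp)) {
      gap <- comp$start[i] - comp$end[i - 1L] - 1L
      run <- if (gap <= max_adjacent_gap) run + 1L else 1L
      best <- max(best, run)
    }
  }
  flag <- best > 4L
  n <- min(best, 4L)
  sub <- c("MYB_RELATED", "R2R3", "R1R2R3", "FOUR_R")[n]
  list(subfamily = sub, n_adjacent = best, flag_gt4 = flag)
}

#' Keep one representative sequence per locus (longest isoform)
#'
#' @param seqs named character vector; isoform suffixes like `.1`, `.2` are
#'   stripped to form the locus id.
#' @param locus optional explicit locus ids aligned with `seqs`.
#' @return named character vector with one (longest) sequence per locus.
#' @export
representative_per_gene <- function(seqs,
                                    locus = sub("\\.[0-9]+$", "",
                                                names(seqs))) {
  ord <- order(locus, -nchar(seqs), names(seqs))
  seqs[ord][!duplicated(locus[ord])]
}

#' Run the family census over a proteome
#'
#' Scans every protein for repeat hits, classifies architectures, and
#' tallies subfamily membership. Deterministic given inputs and parameters.
#'
#' @param proteome named character vector of protein sequences, or path to
#'   a protein FASTA.
#' @param profile a `repeat_profile` from [build_profile()].
#' @param thresholds `"auto"` (default: null-calibrated via
#'   [calibrate_thresholds()]) or a thresholds list.
#' @param max_adjacent_gap see [classify_architecture()].
#' @param one_per_gene when TRUE, keep the longest isoform per locus first.
#' @param seed seed for the automatic null calibration.
#' @return object of class `myb_census`: list with `architectures` (per
#'   protein data frame), `hits` (per-hit data frame, 1-based closed
#'   coordinates), `counts` (per subfamily, family members only), `total`
#'   (family members) and `params`.
#' @export
census <- function(proteome, profile, thresholds = "auto",
                   max_adjacent_gap = 30L, complete_min = 0.8,
                   one_per_gene = FALSE, seed = 1L) {
  if (is.character(proteome) && length(proteome) == 1 &&
      file.exists(proteome)) {
    proteome <- read_fasta_vec(proteome)
  }
  stopifnot(is.character(proteome))
  if (is.null(names(proteome)) && length(proteome) > 0) {
    names(proteome) <- sprintf("seq%04d", seq_along(proteome))
  }
  if (one_per_gene) proteome <- representative_per_gene(proteome)
  if (identical(thresholds, "auto")) {
    thresholds <- calibrate_thresholds(profile, seed = seed)
  }
  arch_rows <- vector("list", length(proteome))
  hit_rows <- list()
  for (i in seq_along(proteome)) {
    id <- names(proteome)[i]
    hits <- scan_repeats(proteome[[i]], profile, thresholds, complete_min)
    cls <- classify_architecture(hits, max_adjacent_gap, complete_min)
    arch_rows[[i]] <- data.frame(
      id = id, subfamily = cls$subfamily,
      n_complete = sum(hits$completeness >= complete_min),
      n_partial = sum(hits$completeness < complete_min),
      n_adjacent = cls$n_adjacent, flag_gt4 = cls$flag_gt4,
      length = nchar(proteome[[i]]), stringsAsFactors = FALSE)
    if (nrow(hits)) {
      hit_rows[[length(hit_rows) + 1L]] <-
        cbind(data.frame(id = id, stringsAsFactors = FALSE), hits)
    }
  }
  arch <- if (length(arch_rows)) do.call(rbind, arch_rows) else
    data.frame(id = character(0), subfamily = character(0),
               n_complete = integer(0), n_partial = integer(0),
               n_adjacent = integer(0), flag_gt4 = logical(0),
               length = integer(0))
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(id = character(0), start = integer(0), end = integer(0),
               score = numeric(0), completeness = numeric(0))
  member_levels <- setdiff(SUBFAMILY_LEVELS, "NOT_MYB")
  counts <- table(factor(arch$subfamily, levels = member_levels))
  structure(list(architectures = arch, hits = hits,
                 counts = stats::setNames(as.integer(counts),
                                          member_levels),
                 total = sum(arch$subfamily != "NOT_MYB"),
                 params = list(thresholds = thresholds,
                               max_adjacent_gap = max_adjacent_gap,
                               complete_min = complete_min)),
            class = "myb_census")
}

#' @export
print.myb_census <- function(x, ...) {
  cat("MYB superfamily census\n")
  cat(sprintf("  proteins scanned : %d\n", nrow(x$architectures)))
  cat(sprintf("  family members   : %d\n", x$total))
  for (s in names(x$counts)) {
    cat(sprintf("    %-12s %d\n", s, x$counts[[s]]))
  }
  invisible(x)
}

#' @export
summary.myb_census <- function(object, ...) {
  cat(sprintf(
    "Census of %d proteins: %d family members (%s); %d non-members\n",
    nrow(object$architectures), object$total,
    paste(sprintf("%s=%d", names(object$counts), object$counts),
          collapse = ", "),
    sum(object$architectures$subfamily == "NOT_MYB")))
  invisible(object)
}
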