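# Synthetic-data generators. These emulate the statistical structure the
# census assumes -- a proteome with planted MYB-repeat architectures, gene
# models on chromosomes, anchor-labelled reference families, a seed
# alignment for the scanning profile, and a qPCR Ct table generated by
# running the 2^-ddCt model in reverse -- with full ground truth, so every
# downstream stage can be verified without external downloads.
#
# All coordinates emitted by this module are 1-based closed intervals, the
# R/Bioconductor convention (IRanges); GFF3 output shares it natively.

SUBFAMILY_LEVELS <- c("MYB_RELATED", "R2R3", "R1R2R3", "FOUR_R",
                      "ATYPICAL", "NOT_MYB")

REPEATS_PER_CLASS <- c(MYB_RELATED = 1L, R2R3 = 2L, R1R2R3 = 3L,
                       FOUR_R = 4L, ATYPICAL = 0L, NOT_MYB = 0L)

#' Default MYB-repeat consensus used by the generators
#'
#' A 52-residue MYB-repeat-like consensus: helix-turn-helix character with
#' the separated tryptophan triplet typical of plant R2 repeats.
#' @export
DEFAULT_REPEAT_CONSENSUS <- paste0(
  "KGPWTEEEDRLLRQAFERLGGRWSQIARHLPGRTDNEIKNYWNSHLSRKLGI")

#' Specify a synthetic MYB-family proteome
#'
#' Bundles and validates the knobs of the proteome generator: how many
#' proteins of each repeat-architecture class to plant, the repeat consensus
#' (50-53 residues, the biological width of one MYB repeat), the
#' per-position substitution rate that makes the planted repeats
#' "imperfect", protein-length and inter-repeat-gap ranges, and the genome
#' geometry used for gene models.
#'
#' @param counts named integer vector over classes
#'   `MYB_RELATED, R2R3, R1R2R3, FOUR_R, ATYPICAL, NOT_MYB` (missing classes
#'   default to 0).
#' @param repeat_consensus amino-acid string, length 50-53.
#' @param substitution_rate per-position substitution probability in `[0,1]`.
#' @param background_length length-2 range (residues) for total protein
#'   length.
#' @param inter_repeat_gap length-2 range (residues) between adjacent
#'   planted repeats.
#' @param n_chromosomes number of chromosomes for gene placement.
#' @param chromosome_length chromosome length in bp.
#' @param seed master integer seed.
#' @return an object of class `family_spec`.
#' @export
family_spec <- function(counts,
                        repeat_consensus = DEFAULT_REPEAT_CONSENSUS,
                        substitution_rate = 0.05,
                        background_length = c(150L, 400L),
                        inter_repeat_gap = c(1L, 10L),
                        n_chromosomes = 8L,
                        chromosome_length = 2e6,
                        seed = 1L) {
  full <- stats::setNames(integer(length(SUBFAMILY_LEVELS)), SUBFAMILY_LEVELS)
  if (is.null(names(counts)) || !all(names(counts) %in% SUBFAMILY_LEVELS)) {
    stop("counts must be named with subfamily classes: ",
         paste(SUBFAMILY_LEVELS, collapse = ", "))
  }
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0)) stop("counts must be non-negative")
  if (sum(full) == 0) stop("at least one protein must be requested")
  w <- nchar(repeat_consensus)
  if (w < 50 || w > 53) {
    stop("repeat_consensus must encode 50-53 amino acid residues, got ", w)
  }
  check_standard_aa(repeat_consensus, "repeat_consensus")
  if (substitution_rate < 0 || substitution_rate > 1) {
    stop("substitution_rate must lie in [0,1]")
  }
  stopifnot(length(background_length) == 2, background_length[1] >= 60,
            background_length[2] >= background_length[1],
            length(inter_repeat_gap) == 2, inter_repeat_gap[1] >= 0,
            inter_repeat_gap[2] >= inter_repeat_gap[1],
            n_chromosomes >= 1, chromosome_length > 0)
  structure(list(counts = full,
                 repeat_consensus = repeat_consensus,
                 substitution_rate = substitution_rate,
                 background_length = as.integer(background_length),
                 inter_repeat_gap = as.integer(inter_repeat_gap),
                 n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length = as.numeric(chromosome_length),
                 seed = as.integer(seed)),
            class = "family_spec")
}

#' Generate one imperfect copy of a repeat consensus
#'
#' Each position is substituted independently with probability
#' `substitution_rate`; the replacement residue is drawn uniformly from the
#' 19 other residues, so a substituted position never equals the consensus.
#' Draws come from the current RNG state (seed at the call site).
#'
#' @param consensus amino-acid string.
#' @param substitution_rate substitution probability in `[0,1]`.
#' @return a string of the same length as `consensus`.
#' @export
generate_repeat <- function(consensus, substitution_rate) {
  if (!is.character(consensus) || length(consensus) != 1 ||
      nchar(consensus) == 0) {
    stop("consensus must be a non-empty amino-acid string")
  }
  if (substitution_rate < 0 || substitution_rate > 1) {
    stop("substitution_rate must lie in [0,1]")
  }
  chars <- strsplit(consensus, "")[[1]]
  hit <- stats::runif(length(chars)) < substitution_rate
  if (any(hit)) {
    repl <- vapply(chars[hit], function(a) {
      sample(setdiff(AA_ALPHABET20, a), 1L)
    }, character(1))
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

# Uniform random background sequence over the 20 residues.
random_aa <- function(n) {
  paste(sample(AA_ALPHABET20, n, replace = TRUE), collapse = "")
}

# Uniform integer draw on [lo, hi]; safe when lo == hi (unlike sample()).
sample_range <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

#' Generate a synthetic proteome with planted repeat architectures
#'
#' Every requested protein of class k carries k complete adjacent copies of
#' the (mutated) repeat consensus embedded in uniform random background,
#' with inter-repeat gaps drawn from the spec range. `ATYPICAL` proteins
#' carry a single partial repeat covering 40-60 percent of the consensus
#' (mirroring family members with only part of the R2/R3 repeats);
#' `NOT_MYB` proteins are pure background. The CDS is a fixed-codon
#' back-translation of each protein plus a stop, so CDS length is
#' `3 * protein_length + 3`.
#'
#' @param spec a [family_spec()].
#' @return list with `proteins` and `cds` (named character vectors) and
#'   `truth` (list of `proteins` and `repeats` data frames; 1-based closed
#'   repeat coordinates).
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  w <- nchar(spec$repeat_consensus)
  with_seed(derive_seed(spec$seed, "proteome"), {
    ids <- character(0); classes <- character(0)
    proteins <- character(0)
    rep_rows <- list()
    idx <- 0L
    for (cls in SUBFAMILY_LEVELS) {
      for (k in seq_len(spec$counts[[cls]])) {
        idx <- idx + 1L
        id <- sprintf("SYNP.%s%03d", c(MYB_RELATED = "1R", R2R3 = "2R",
                                       R1R2R3 = "3R", FOUR_R = "4R",
                                       ATYPICAL = "AT", NOT_MYB = "BG")[[cls]],
                      k)
        n_rep <- REPEATS_PER_CLASS[[cls]]
        if (cls == "ATYPICAL") {
          pw <- round(stats::runif(1, 0.4, 0.6) * w)
          segs <- substr(generate_repeat(spec$repeat_consensus,
                                         spec$substitution_rate), 1L, pw)
          widths <- pw
          complete <- FALSE
        } else if (n_rep > 0) {
          segs <- vapply(seq_len(n_rep), function(i) {
            generate_repeat(spec$repeat_consensus, spec$substitution_rate)
          }, character(1))
          widths <- rep(w, n_rep)
          complete <- TRUE
        } else {
          segs <- character(0); widths <- integer(0); complete <- logical(0)
        }
        n_seg <- length(segs)
        gaps <- if (n_seg > 1) {
          sample_range(spec$inter_repeat_gap[1], spec$inter_repeat_gap[2],
                       n_seg - 1L)
        } else integer(0)
        required <- sum(widths) + sum(gaps)
        # protein length: uniform over the part of the requested range that
        # can host the planted repeats plus a small flanking margin
        lo <- max(spec$background_length[1], required + 20L)
        hi <- spec$background_length[2]
        if (required > hi - 2L) {
          stop(sprintf(
            "impossible geometry for %s: planted repeats span %d residues but maximal protein budget is %d",
            id, required, hi))
        }
        L <- if (lo <= hi) sample_range(lo, hi) else hi
        bg <- strsplit(random_aa(L), "")[[1]]
        if (n_seg > 0) {
          offset <- sample_range(1L, L - required - 1L)
          pos <- offset + 1L
          for (i in seq_len(n_seg)) {
            s <- pos; e <- pos + widths[i] - 1L
            bg[s:e] <- strsplit(segs[i], "")[[1]]
            rep_rows[[length(rep_rows) + 1L]] <- data.frame(
              id = id, start = s, end = e,
              complete = if (length(complete) == 1) complete else TRUE,
              stringsAsFactors = FALSE)
            pos <- e + 1L + if (i < n_seg) gaps[i] else 0L
          }
        }
        ids <- c(ids, id); classes <- c(classes, cls)
        proteins <- c(proteins, paste(bg, collapse = ""))
      }
    }
    names(proteins) <- ids
    cds <- vapply(proteins, backtranslate, character(1))
    truth_prot <- data.frame(id = ids, class = classes,
                             n_repeats = REPEATS_PER_CLASS[classes],
                             length = nchar(proteins),
                             stringsAsFactors = FALSE)
    truth_rep <- if (length(rep_rows)) do.call(rbind, rep_rows) else
      data.frame(id = character(0), start = integer(0), end = integer(0),
                 complete = logical(0))
    list(proteins = proteins, cds = cds,
         truth = list(proteins = truth_prot, repeats = truth_rep))
  })
}

#' Back-translate a protein with a fixed codon table
#' @param protein amino-acid string.
#' @return CDS string (`3 * nchar(protein) + 3` nt, including a stop codon).
#' @export
backtranslate <- function(protein) {
  chars <- strsplit(protein, "")[[1]]
  paste0(paste(BACKTRANSLATE_CODON[chars], collapse = ""), STOP_CODON)
}

#' Generate a GFF3 gene-model file for a synthetic proteome
#'
#' Genes are placed on chromosomes uniformly without overlap; each mRNA
#' carries the requested exon count, exon spans sum to the CDS length, and
#' strands are assigned at random. The GFF3 hierarchy is
#' gene -> mRNA -> exon/CDS with 1-based closed coordinates.
#'
#' @param spec a [family_spec()].
#' @param proteome result of [generate_proteome()].
#' @param exons_per_gene integer, or named integer vector per gene id.
#' @param intron_length range of intron lengths (bp).
#' @param path optional output path; when given the GFF3 is written there.
#' @return list with `gff_lines`, `models` (gene, chromosome, strand, start,
#'   end, n_exons) and `chromosome_lengths`.
#' @export
generate_gene_models <- function(spec, proteome, exons_per_gene = 3L,
                                 intron_length = c(80L, 500L), path = NULL) {
  stopifnot(inherits(spec, "family_spec"))
  ids <- names(proteome$cds)
  if (length(exons_per_gene) == 1L) {
    exons_per_gene <- stats::setNames(rep(as.integer(exons_per_gene),
                                          length(ids)), ids)
  }
  if (any(exons_per_gene < 1L)) stop("exons_per_gene must be >= 1")
  with_seed(derive_seed(spec$seed, "gene_models"), {
    chrom <- sample(sprintf("chr%d", seq_len(spec$n_chromosomes)),
                    length(ids), replace = TRUE)
    cursor <- stats::setNames(rep(1, spec$n_chromosomes),
                              sprintf("chr%d", seq_len(spec$n_chromosomes)))
    lines <- c("##gff-version 3",
               sprintf("##sequence-region chr%d 1 %d",
                       seq_len(spec$n_chromosomes),
                       as.integer(spec$chromosome_length)))
    rows <- list()
    for (i in seq_along(ids)) {
      id <- ids[i]
      cds_len <- nchar(proteome$cds[[id]])
      n_ex <- exons_per_gene[[id]]
      if (cds_len < 3L * n_ex) {
        stop("CDS of ", id, " too short for ", n_ex, " exons")
      }
      # random composition of the CDS length into n_ex exon spans (>= 3 bp)
      cuts <- sort(sample(seq_len(cds_len - 1L), n_ex - 1L))
      ex_len <- diff(c(0L, cuts, cds_len))
      while (any(ex_len < 3L)) {
        cuts <- sort(sample(seq_len(cds_len - 1L), n_ex - 1L))
        ex_len <- diff(c(0L, cuts, cds_len))
      }
      in_len <- if (n_ex > 1) {
        sample_range(intron_length[1], intron_length[2], n_ex - 1L)
      } else integer(0)
      span <- sum(ex_len) + sum(in_len)
      gap <- sample_range(200L, 2000L)
      start <- cursor[[chrom[i]]] + gap
      end <- start + span - 1L
      if (end > spec$chromosome_length) {
        stop("chromosome capacity exceeded on ", chrom[i],
             "; increase chromosome_length or reduce gene count")
      }
      cursor[[chrom[i]]] <- end
      strand <- sample(c("+", "-"), 1L)
      ex_start <- start + c(0L, cumsum(ex_len[-n_ex] + in_len))
      ex_end <- ex_start + ex_len - 1L
      mrna <- paste0(id, ".mRNA1")
      lines <- c(lines,
        sprintf("%s\tsynth\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
                chrom[i], start, end, strand, id, id),
        sprintf("%s\tsynth\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                chrom[i], start, end, strand, mrna, id),
        sprintf("%s\tsynth\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                chrom[i], ex_start, ex_end, strand, id,
                seq_len(n_ex), mrna),
        sprintf("%s\tsynth\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
                chrom[i], ex_start, ex_end, strand, id, mrna))
      rows[[i]] <- data.frame(gene = id, chromosome = chrom[i],
                              strand = strand, start = start, end = end,
                              n_exons = n_ex, cds_length = cds_len,
                              stringsAsFactors = FALSE)
    }
    models <- do.call(rbind, rows)
    if (!is.null(path)) writeLines(lines, path)
    list(gff_lines = lines, models = models,
         chromosome_lengths = stats::setNames(
           rep(spec$chromosome_length, spec$n_chromosomes),
           sprintf("chr%d", seq_len(spec$n_chromosomes))))
  })
}

#' Generate a qPCR Ct table by running the 2^-ddCt model in reverse
#'
#' For each (gene, cultivar, stage) condition with planted fold change f,
#' target Ct values satisfy
#' `Ct_target = Ct_ref + dCt_calibrator - log2(f) + N(0, ct_noise_sd)` per
#' replicate; the calibrator condition (first stage of each gene within each
#' cultivar) has fold 1 by construction. Reference-gene Ct values carry the
#' same replicate noise. At `ct_noise_sd = 0` the downstream 2^-ddCt
#' quantification recovers every planted fold exactly.
#'
#' @param fold_changes data frame with columns `gene`, `cultivar`,
#'   `stage_DAFB`, `fold` (fold > 0; the first stage of each gene/cultivar
#'   must have fold 1).
#' @param reference_gene reference (housekeeping) gene name.
#' @param ct_noise_sd replicate noise SD in cycles.
#' @param n_replicates replicates per condition (biological repeats).
#' @param seed integer seed.
#' @return data frame with columns `gene, cultivar, stage_DAFB, replicate,
#'   Ct` including reference-gene rows.
#' @export
generate_qpcr_table <- function(fold_changes, reference_gene = "RPII",
                                ct_noise_sd = 0.2, n_replicates = 3L,
                                seed = 1L) {
  req <- c("gene", "cultivar", "stage_DAFB", "fold")
  stopifnot(all(req %in% names(fold_changes)))
  if (any(fold_changes$fold <= 0)) stop("fold changes must be positive")
  if (n_replicates < 1) stop("need at least one replicate")
  fc <- fold_changes[order(fold_changes$gene, fold_changes$cultivar,
                           fold_changes$stage_DAFB), , drop = FALSE]
  first_stage <- !duplicated(fc[c("gene", "cultivar")])
  if (any(abs(fc$fold[first_stage] - 1) > 1e-12)) {
    stop("the calibrator condition (first stage per gene and cultivar) ",
         "must have fold 1")
  }
  with_seed(derive_seed(seed, "qpcr"), {
    genes <- unique(fc$gene)
    dct_cal <- stats::setNames(stats::runif(length(genes), 2, 8), genes)
    conds <- unique(fc[c("cultivar", "stage_DAFB")])
    rows <- list()
    for (j in seq_len(nrow(conds))) {
      cv <- conds$cultivar[j]; st <- conds$stage_DAFB[j]
      ct_ref <- 20 + stats::rnorm(n_replicates, 0, ct_noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = reference_gene, cultivar = cv, stage_DAFB = st,
        replicate = seq_len(n_replicates), Ct = ct_ref,
        stringsAsFactors = FALSE)
      sub <- fc[fc$cultivar == cv & fc$stage_DAFB == st, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        g <- sub$gene[i]
        ct <- ct_ref + dct_cal[[g]] - log2(sub$fold[i]) +
          stats::rnorm(n_replicates, 0, ct_noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, cultivar = cv, stage_DAFB = st,
          replicate = seq_len(n_replicates), Ct = ct,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate a gap-free seed alignment of repeat copies
#'
#' Mutated copies of the repeat consensus, all the same length, suitable for
#' building the scanning profile.
#'
#' @param consensus amino-acid string.
#' @param n number of sequences.
#' @param substitution_rate per-position substitution probability.
#' @param seed integer seed.
#' @return named character vector of aligned sequences.
#' @export
generate_seed_alignment <- function(consensus = DEFAULT_REPEAT_CONSENSUS,
                                    n = 12L, substitution_rate = 0.1,
                                    seed = 1L) {
  with_seed(derive_seed(seed, "seed_alignment"), {
    out <- vapply(seq_len(n), function(i) {
      generate_repeat(consensus, substitution_rate)
    }, character(1))
    stats::setNames(out, sprintf("seedrep%02d", seq_len(n)))
  })
}

#' Generate anchor-seeded sequence families for classification benchmarks
#'
#' Each group descends from its own random founder sequence; members are
#' independent mutated copies of the founder. A subset of members per group
#' is designated as labelled anchors (reference proteins), the rest are
#' unlabelled queries. Species-specific groups receive no anchors, emulating
#' lineage-specific family members with no reference relative.
#'
#' @param n_groups number of anchored groups.
#' @param members_per_group query members per group.
#' @param anchors_per_group anchors per group.
#' @param n_specific number of species-specific (anchorless) queries, each
#'   from its own founder.
#' @param seq_length founder length (residues).
#' @param divergence per-position substitution rate from founder.
#' @param group_labels optional character vector of group names
#'   (default C1..Cn).
#' @param prefix id prefix for this benchmark's sequences.
#' @param seed integer seed.
#' @return list with `seqs` (named vector), `anchors` (data frame id,
#'   group), `truth` (data frame id, group, is_anchor; species-specific
#'   queries have group `"species-specific"`).
#' @export
generate_group_benchmark <- function(n_groups = 6L, members_per_group = 4L,
                                     anchors_per_group = 2L, n_specific = 3L,
                                     seq_length = 120L, divergence = 0.05,
                                     group_labels = NULL, prefix = "FAM",
                                     seed = 1L) {
  if (is.null(group_labels)) group_labels <- sprintf("C%d", seq_len(n_groups))
  stopifnot(length(group_labels) == n_groups)
  with_seed(derive_seed(seed, paste0("groups_", prefix)), {
    seqs <- character(0); rows <- list()
    for (g in seq_len(n_groups)) {
      founder <- random_aa(seq_length)
      n_tot <- members_per_group + anchors_per_group
      for (m in seq_len(n_tot)) {
        is_anchor <- m <= anchors_per_group
        id <- sprintf("%s_%s_%s%02d", prefix, group_labels[g],
                      if (is_anchor) "anchor" else "query", m)
        seqs[[id]] <- generate_repeat(founder, divergence)
        rows[[length(rows) + 1L]] <- data.frame(
          id = id, group = group_labels[g], is_anchor = is_anchor,
          stringsAsFactors = FALSE)
      }
    }
    for (s in seq_len(n_specific)) {
      founder <- random_aa(seq_length)
      id <- sprintf("%s_specific_query%02d", prefix, s)
      seqs[[id]] <- generate_repeat(founder, divergence)
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, group = "species-specific", is_anchor = FALSE,
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    list(seqs = seqs,
         anchors = truth[truth$is_anchor, c("id", "group")],
         truth = truth)
  })
}
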