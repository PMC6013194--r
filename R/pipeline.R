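# Pipeline orchestration: generate or validate an input bundle, run every
# census stage in dependency order, and write a manifest with content
# checksums so a run is verifiably reproducible (same config + seed =>
# identical manifest).

#' Generate a complete synthetic input bundle on disk
#'
#' Writes every input the census pipeline consumes -- protein FASTA, CDS
#' FASTA, GFF3 gene models, seed alignment, anchor FASTA + label TSV, qPCR
#' Ct table -- plus a ground-truth JSON, and returns a ready-to-run
#' pipeline config. Anchors are noisy copies of selected family members:
#' stage-1 anchors (groups C1, C2, ...) descend from R2R3/R1R2R3 members,
#' stage-2 anchors (CCA1-like, CPC-like, TBP-like, I-box-binding-like,
#' R-R-type) from MYB-related members; two anchor copies per group so
#' within-group anchor distances are defined.
#'
#' @param dir output directory (created if needed).
#' @param seed master integer seed.
#' @param spec optional [family_spec()]; the default plants 60 proteins
#'   (16 MYB-related, 20 R2R3, 3 R1R2R3, 1 4R, 4 atypical, 16 background)
#'   at substitution rate 0.05.
#' @param anchor_divergence substitution rate of anchor copies.
#' @param ct_noise_sd replicate noise (cycles) of the Ct table.
#' @return a pipeline config list (see [run_pipeline()]).
#' @export
synth_bundle <- function(dir, seed = 42L, spec = NULL,
                         anchor_divergence = 0.05, ct_noise_sd = 0.2) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(spec)) {
    spec <- family_spec(c(MYB_RELATED = 16, R2R3 = 20, R1R2R3 = 3,
                          FOUR_R = 1, ATYPICAL = 4, NOT_MYB = 16),
                        substitution_rate = 0.05, seed = seed)
  }
  pr <- generate_proteome(spec)
  write_fasta_vec(pr$proteins, file.path(dir, "proteome.fa"))
  write_fasta_vec(pr$cds, file.path(dir, "cds.fa"))
  gm <- generate_gene_models(spec, pr, exons_per_gene = 3L,
                             path = file.path(dir, "models.gff3"))
  aln <- generate_seed_alignment(spec$repeat_consensus, seed = seed)
  write_fasta_vec(aln, file.path(dir, "seed_alignment.fa"))

  truth_prot <- pr$truth$proteins
  make_anchors <- function(source_ids, labels, subfam, stream) {
    with_seed(derive_seed(seed, stream), {
      rows <- list(); seqs <- character(0)
      for (i in seq_along(source_ids)) {
        for (cp in 1:2) {
          aid <- sprintf("ANC.%s.%d", gsub("[^A-Za-z0-9]", "",
                                           labels[i]), cp * 100 + i)
          seqs[[aid]] <- generate_repeat(pr$proteins[[source_ids[i]]],
                                         anchor_divergence)
          rows[[length(rows) + 1L]] <- data.frame(
            id = aid, subfamily = subfam, group = labels[i],
            stringsAsFactors = FALSE)
        }
      }
      list(seqs = seqs, tsv = do.call(rbind, rows))
    })
  }
  r2r3_ids <- truth_prot$id[truth_prot$class %in% c("R2R3", "R1R2R3")]
  src1 <- r2r3_ids[seq(1, length(r2r3_ids), by = 3)]
  a1 <- make_anchors(src1, sprintf("C%d", seq_along(src1)), "R2R3",
                     "anchors_stage1")
  rel_ids <- truth_prot$id[truth_prot$class == "MYB_RELATED"]
  lab2 <- c("CCA1-like", "CPC-like", "TBP-like", "I-box-binding-like",
            "R-R-type")
  src2 <- rel_ids[seq_len(min(length(lab2), length(rel_ids)))]
  a2 <- make_anchors(src2, lab2[seq_along(src2)], "MYB_RELATED",
                     "anchors_stage2")
  write_fasta_vec(c(a1$seqs, a2$seqs), file.path(dir, "anchors.fa"))
  write_tsv(rbind(a1$tsv, a2$tsv), file.path(dir, "anchors.tsv"))

  # qPCR truth: planted decreasing / increasing / flat / mixed patterns
  stages <- c(51, 64, 75, 84, 93)
  exp_genes <- utils::head(truth_prot$id[truth_prot$class == "R2R3"], 6)
  patterns <- list(c(1, .5, .25, .125, .0625), c(1, 2, 4, 8, 16),
                   c(1, 1, 1, 1, 1), c(1, 2, 1, 2, 1),
                   c(1, .7, .49, .343, .24), c(1, 1.5, 2.25, 3.375, 5))
  fc <- do.call(rbind, lapply(seq_along(exp_genes), function(i) {
    do.call(rbind, lapply(c("ZX", "YJH"), function(cv) {
      data.frame(gene = exp_genes[i], cultivar = cv, stage_DAFB = stages,
                 fold = patterns[[i]], stringsAsFactors = FALSE)
    }))
  }))
  ct <- generate_qpcr_table(fc, reference_gene = "RPII",
                            ct_noise_sd = ct_noise_sd, seed = seed)
  write_tsv(ct, file.path(dir, "ct_table.tsv"))

  # second species: diverged copies of half the family members
  memb <- truth_prot$id[truth_prot$class != "NOT_MYB"]
  src_b <- memb[seq(1, length(memb), by = 2)]
  spB <- with_seed(derive_seed(seed, "species_b"), {
    out <- vapply(src_b, function(id)
      generate_repeat(pr$proteins[[id]], 0.1), character(1))
    stats::setNames(out, sub("^SYNP", "SYNB", src_b))
  })
  write_fasta_vec(spB, file.path(dir, "species_b.fa"))

  truth <- list(proteins = pr$truth$proteins, repeats = pr$truth$repeats,
                gene_models = gm$models, fold_changes = fc,
                species_b_source = stats::setNames(src_b, names(spB)))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA)

  list(proteome = file.path(dir, "proteome.fa"),
       cds = file.path(dir, "cds.fa"),
       gff3 = file.path(dir, "models.gff3"),
       seed_alignment = file.path(dir, "seed_alignment.fa"),
       anchors_fasta = file.path(dir, "anchors.fa"),
       anchors_tsv = file.path(dir, "anchors.tsv"),
       ct_table = file.path(dir, "ct_table.tsv"),
       second_proteome = file.path(dir, "species_b.fa"),
       chromosome_lengths = gm$chromosome_lengths,
       seed = seed)
}

#' Validate a pipeline configuration and its inputs
#'
#' Report-only cross-checks: input files exist, FASTA and GFF3 gene ids
#' agree, anchor labels are well-formed, and the Ct table is complete.
#'
#' @param config pipeline config list (see [run_pipeline()]).
#' @return data frame with columns `check`, `status`
#'   (`"pass"`/`"warn"`/`"fail"`) and `detail`.
#' @export
validate_inputs <- function(config) {
  rows <- list()
  note <- function(check, status, detail = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, status = status, detail = detail,
      stringsAsFactors = FALSE)
  }
  paths <- c("proteome", "seed_alignment")
  for (p in paths) {
    if (is.null(config[[p]]) || !file.exists(config[[p]])) {
      note(paste0(p, "_exists"), "fail",
           paste0("missing required input: ", p))
    } else note(paste0(p, "_exists"), "pass")
  }
  for (p in c("gff3", "anchors_fasta", "anchors_tsv", "ct_table",
              "second_proteome")) {
    if (is.null(config[[p]]) || !file.exists(config[[p]])) {
      note(paste0(p, "_exists"), "warn",
           paste0("optional input absent: ", p,
                  "; dependent stage will be skipped"))
    } else note(paste0(p, "_exists"), "pass")
  }
  if (!is.null(config$proteome) && file.exists(config$proteome) &&
      !is.null(config$gff3) && file.exists(config$gff3)) {
    prot <- read_fasta_vec(config$proteome)
    models <- parse_gff3(config$gff3)
    missing <- setdiff(names(prot), models$genes$gene)
    if (length(missing)) {
      note("proteome_gff3_ids", "warn",
           paste0("proteome ids absent from GFF3: ",
                  paste(utils::head(missing, 10), collapse = ", ")))
    } else note("proteome_gff3_ids", "pass")
  }
  if (!is.null(config$anchors_tsv) && file.exists(config$anchors_tsv)) {
    an <- utils::read.delim(config$anchors_tsv, stringsAsFactors = FALSE)
    if (!all(c("id", "subfamily", "group") %in% names(an))) {
      note("anchor_columns", "fail",
           "anchors TSV must have id, subfamily, group columns")
    } else if (any(!nzchar(an$group)) || anyNA(an$group)) {
      note("anchor_labels", "fail", "empty or missing anchor group labels")
    } else note("anchor_labels", "pass")
    if (!is.null(config$anchors_fasta) &&
        file.exists(config$anchors_fasta)) {
      fa <- read_fasta_vec(config$anchors_fasta)
      if (!setequal(names(fa), an$id)) {
        note("anchor_ids", "fail",
             "anchor FASTA and TSV ids do not agree")
      } else note("anchor_ids", "pass")
    }
  }
  if (!is.null(config$ct_table) && file.exists(config$ct_table)) {
    ct <- utils::read.delim(config$ct_table, stringsAsFactors = FALSE)
    need <- c("gene", "cultivar", "stage_DAFB", "replicate", "Ct")
    if (!all(need %in% names(ct))) {
      note("ct_columns", "fail",
           paste0("Ct table needs columns: ", paste(need, collapse = ", ")))
    } else {
      tab <- table(ct$gene, paste(ct$cultivar, ct$stage_DAFB))
      if (length(unique(as.integer(tab))) > 1) {
        note("ct_completeness", "warn",
             "unbalanced replicate counts across conditions")
      } else note("ct_completeness", "pass")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full census pipeline from a config
#'
#' Executes the stages in dependency order -- repeat scan and census,
#' two-stage group classification, motif discovery, gene structure and
#' chromosome distribution, homology (orthologs/paralogs), physicochemical
#' profiling, relative expression -- writing each stage's outputs before
#' the next starts, and finishes with a manifest JSON listing every
#' artifact with an md5 checksum. Optional inputs that are absent skip
#' their stage with a warning. A stage failure aborts with the stage
#' named; outputs of earlier stages are retained.
#'
#' @param config list with input paths (`proteome`, `seed_alignment`;
#'   optional `gff3`, `anchors_fasta`, `anchors_tsv`, `ct_table`,
#'   `second_proteome`, `chromosome_lengths`), `out_dir`, `seed`, and
#'   optional stage parameters (`min_score`, `max_adjacent_gap`,
#'   `complete_min`, `n_boot`, `max_motifs`, `terminal_fraction`,
#'   `inflation`, `reference_gene`, `calibrator`, `trend_tolerance`).
#' @param quiet suppress progress messages.
#' @return object of class `myb_pipeline`: list with `manifest`, `census`,
#'   `groups`, `motifs`, `structure`, `homology`, `physchem`,
#'   `expression` (stages that ran), and `out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(!is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else config$seed
  par <- function(name, default) {
    if (is.null(config[[name]])) default else config[[name]]
  }
  say <- function(...) {
    if (!quiet) message(format(Sys.time(), "%H:%M:%S "), ...)
  }
  artifacts <- character(0)
  emit <- function(path) artifacts <<- c(artifacts, path)
  run_stage <- function(name, expr) {
    say("stage ", name)
    tryCatch(expr, error = function(e) {
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  result <- list(out_dir = out_dir)

  # --- scan + census ------------------------------------------------------
  cz <- run_stage("census", {
    prot <- read_fasta_vec(config$proteome)
    profile <- build_profile(read_fasta_vec(config$seed_alignment))
    thr <- par("min_score", "auto")
    cz <- census(prot, profile,
                 thresholds = thr,
                 max_adjacent_gap = par("max_adjacent_gap", 30L),
                 complete_min = par("complete_min", 0.8),
                 seed = seed)
    arch_path <- file.path(out_dir, "architecture.tsv")
    hits <- cz$hits
    write_tsv(cz$architectures, arch_path)
    emit(arch_path)
    hits_path <- file.path(out_dir, "repeat_hits.tsv")
    hits$score <- format_num(hits$score)
    hits$completeness <- format_num(hits$completeness)
    write_tsv(hits, hits_path); emit(hits_path)
    census_path <- file.path(out_dir, "census.json")
    jsonlite::write_json(list(counts = as.list(cz$counts),
                              total = cz$total,
                              n_scanned = nrow(cz$architectures)),
                         census_path, auto_unbox = TRUE, digits = NA)
    emit(census_path)
    cz
  })
  result$census <- cz
  members <- cz$architectures$id[cz$architectures$subfamily != "NOT_MYB"]
  prot <- read_fasta_vec(config$proteome)

  # --- two-stage classification ------------------------------------------
  if (!is.null(config$anchors_fasta) && file.exists(config$anchors_fasta) &&
      !is.null(config$anchors_tsv) && file.exists(config$anchors_tsv)) {
    result$groups <- run_stage("classify", {
      an_seqs <- read_fasta_vec(config$anchors_fasta)
      an_tab <- utils::read.delim(config$anchors_tsv,
                                  stringsAsFactors = FALSE)
      stage1 <- an_tab$subfamily %in% c("R2R3", "R1R2R3")
      a1 <- list(seqs = an_seqs[an_tab$id[stage1]],
                 labels = stats::setNames(an_tab$group[stage1],
                                          an_tab$id[stage1]))
      a2 <- list(seqs = an_seqs[an_tab$id[!stage1]],
                 labels = stats::setNames(an_tab$group[!stage1],
                                          an_tab$id[!stage1]))
      grp <- two_stage_classify(prot[members], a1, a2,
                                n_boot = par("n_boot", 100L), seed = seed)
      gpath <- file.path(out_dir, "groups.tsv")
      g <- grp$assignments
      g$nearest_distance <- format_num(g$nearest_distance)
      write_tsv(g, gpath); emit(gpath)
      ape::write.tree(grp$trees$stage1,
                      file.path(out_dir, "tree_stage1.nwk"))
      emit(file.path(out_dir, "tree_stage1.nwk"))
      if (!is.null(grp$trees$stage2)) {
        ape::write.tree(grp$trees$stage2,
                        file.path(out_dir, "tree_stage2.nwk"))
        emit(file.path(out_dir, "tree_stage2.nwk"))
      }
      grp
    })
  } else {
    warning("anchor inputs absent; classification stage skipped")
  }

  # --- motif discovery ----------------------------------------------------
  result$motifs <- run_stage("motifs", {
    mot <- discover_motifs(prot[members],
                           max_motifs = par("max_motifs", 15L),
                           seed = seed)
    meme_path <- file.path(out_dir, "motifs_meme.txt")
    write_meme_minimal(mot, meme_path); emit(meme_path)
    occ <- do.call(rbind, lapply(mot, function(m)
      cbind(m$occurrences, motif = m$id, width = m$width)))
    if (!is.null(occ)) occ$posterior <- format_num(occ$posterior)
    occ_path <- file.path(out_dir, "motif_occurrences.tsv")
    write_tsv(if (is.null(occ)) data.frame() else occ, occ_path)
    emit(occ_path)
    arch <- motif_architectures(mot, ids = members)
    ap <- file.path(out_dir, "motif_architectures.tsv")
    write_tsv(arch, ap); emit(ap)
    for (m in mot) {
      lp <- file.path(out_dir, sprintf("logo_motif%d.svg", m$id))
      write_logo_svg(m, lp); emit(lp)
    }
    mot
  })

  # --- gene structure -----------------------------------------------------
  if (!is.null(config$gff3) && file.exists(config$gff3)) {
    result$structure <- run_stage("structure", {
      models <- parse_gff3(config$gff3)
      st <- gene_structure_table(models)
      sp <- file.path(out_dir, "gene_structure.tsv")
      write_tsv(st, sp); emit(sp)
      lens <- config$chromosome_lengths
      if (is.null(lens)) {
        lens <- tapply(models$genes$end, models$genes$chromosome, max)
      }
      dist <- chromosome_distribution(
        models, lens, terminal_fraction = par("terminal_fraction", 0.25))
      dp <- file.path(out_dir, "chromosome_distribution.tsv")
      pos <- dist$positions
      pos$relative <- format_num(pos$relative)
      write_tsv(pos, dp); emit(dp)
      cp <- file.path(out_dir, "chromosomes.svg")
      write_chromosome_svg(dist, lens, cp); emit(cp)
      list(models = models, structure = st, distribution = dist)
    })
  } else {
    warning("GFF3 absent; structure stage skipped")
  }

  # --- homology -----------------------------------------------------------
  if (!is.null(config$second_proteome) &&
      file.exists(config$second_proteome)) {
    result$homology <- run_stage("homology", {
      spB <- read_fasta_vec(config$second_proteome)
      spA <- prot[members]
      cross <- all_vs_all(spA, spB, seed = seed)
      withinA <- all_vs_all(spA, spA, seed = seed)
      withinB <- all_vs_all(spB, spB, seed = seed)
      edges <- rbind(cross, withinA, withinB)
      ep <- file.path(out_dir, "homology_edges.tsv")
      e <- edges
      e$score <- format_num(e$score); e$weight <- format_num(e$weight)
      write_tsv(e, ep); emit(ep)
      pairs <- rbh(cross)
      cl <- mcl(edges, inflation = par("inflation", 2.0))
      called <- call_pairs(cl, edges, pairs,
                           species = stats::setNames(
                             c(rep("A", length(spA)), rep("B", length(spB))),
                             c(names(spA), names(spB))))
      op <- file.path(out_dir, "orthologs.tsv")
      o <- called$orthologs; o$weight <- format_num(o$weight)
      write_tsv(o, op); emit(op)
      pp <- file.path(out_dir, "paralogs.tsv")
      p2 <- called$paralogs; p2$weight <- format_num(p2$weight)
      write_tsv(p2, pp); emit(pp)
      clp <- file.path(out_dir, "clusters.tsv")
      write_tsv(data.frame(id = names(cl$membership),
                           cluster = unname(cl$membership)), clp)
      emit(clp)
      c(called, list(clusters = cl, rbh = pairs))
    })
  } else {
    warning("second proteome absent; homology stage skipped")
  }

  # --- physicochemical profile -------------------------------------------
  result$physchem <- run_stage("protparam", {
    pp <- protparam_profile(prot[members])
    path <- file.path(out_dir, "physchem.tsv")
    tab <- pp$profile
    for (col in c("mw", "pi", "gravy", "instability")) {
      tab[[col]] <- format_num(tab[[col]])
    }
    write_tsv(tab, path); emit(path)
    sp <- file.path(out_dir, "physchem_summary.json")
    jsonlite::write_json(pp$summary, sp, digits = 6)
    emit(sp)
    pp
  })

  # --- expression ---------------------------------------------------------
  if (!is.null(config$ct_table) && file.exists(config$ct_table)) {
    result$expression <- run_stage("expression", {
      er <- relative_expression(config$ct_table,
                                reference_gene = par("reference_gene",
                                                     "RPII"),
                                calibrator = par("calibrator",
                                                 "first_stage"),
                                tolerance = par("trend_tolerance", 0.05))
      fp <- file.path(out_dir, "expression.tsv")
      f <- er$folds
      for (col in c("delta_ct_mean", "ddct", "fold", "fold_se",
                    "fold_lo", "fold_hi")) {
        f[[col]] <- format_num(f[[col]])
      }
      write_tsv(f, fp); emit(fp)
      tp <- file.path(out_dir, "trends.tsv")
      write_tsv(er$trends, tp); emit(tp)
      er
    })
  } else {
    warning("Ct table absent; expression stage skipped")
  }

  # --- manifest -----------------------------------------------------------
  say("writing manifest")
  sums <- tools::md5sum(artifacts)
  manifest <- list(
    seed = seed,
    files = data.frame(name = basename(artifacts),
                       md5 = unname(sums),
                       bytes = unname(file.size(artifacts)),
                       stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  result$manifest <- manifest
  class(result) <- "myb_pipeline"
  result
}

#' @export
print.myb_pipeline <- function(x, ...) {
  cat("census pipeline run:", x$out_dir, "\n")
  cat(sprintf("  artifacts: %d (see manifest.json)\n",
              nrow(x$manifest$files)))
  ran <- intersect(c("census", "groups", "motifs", "structure", "homology",
                     "physchem", "expression"), names(x))
  cat("  stages   :", paste(ran, collapse = ", "), "\n")
  invisible(x)
}
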