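# Gene-model ingestion (GFF3 via rtracklayer), exon/intron derivation, and
# chromosome-distribution summaries. Coordinates are 1-based closed
# throughout, as in GFF3 itself.

#' Parse a GFF3 file into per-gene models
#'
#' Reads gene/mRNA/exon (and CDS when present) features and keeps one
#' representative mRNA per gene: the one with the longest summed CDS
#' (falling back to exon span), ties broken by lexicographic mRNA id.
#'
#' @param path GFF3 file.
#' @return object of class `gene_models`: list with `genes` (gene,
#'   chromosome, strand, mrna, start, end, n_exons) and `exons` (gene,
#'   start, end, genomic order) data frames.
#' @export
parse_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p)
    if (length(p)) as.character(p)[1] else NA_character_, character(1))
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(genes) == 0) stop("no gene features found in ", path)
  unknown <- setdiff(stats::na.omit(exons$Parent), mrnas$ID)
  if (length(unknown)) {
    stop("format error: exon(s) with unknown Parent: ",
         paste(unknown, collapse = ", "))
  }
  # representative mRNA per gene
  mrna_len <- vapply(seq_len(nrow(mrnas)), function(i) {
    id <- mrnas$ID[i]
    sub <- cds[cds$Parent == id, , drop = FALSE]
    if (nrow(sub) == 0) sub <- exons[exons$Parent == id, , drop = FALSE]
    sum(sub$end - sub$start + 1)
  }, numeric(1))
  ord <- order(mrnas$Parent, -mrna_len, mrnas$ID)
  rep_mrna <- mrnas[ord, ][!duplicated(mrnas$Parent[ord]), , drop = FALSE]

  gene_rows <- list(); exon_rows <- list()
  for (i in seq_len(nrow(rep_mrna))) {
    gid <- rep_mrna$Parent[i]
    g <- genes[genes$ID == gid, , drop = FALSE]
    if (nrow(g) == 0) stop("mRNA ", rep_mrna$ID[i], " has unknown gene ",
                           "Parent ", gid)
    ex <- exons[exons$Parent == rep_mrna$ID[i], , drop = FALSE]
    if (nrow(ex) == 0) stop("representative mRNA of ", gid, " has no exons")
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      stop("overlapping exons in gene ", gid)
    }
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene = gid, chromosome = as.character(g$seqnames[1]),
      strand = as.character(g$strand[1]), mrna = rep_mrna$ID[i],
      start = g$start[1], end = g$end[1], n_exons = nrow(ex),
      stringsAsFactors = FALSE)
    exon_rows[[length(exon_rows) + 1L]] <- data.frame(
      gene = gid, start = ex$start, end = ex$end,
      stringsAsFactors = FALSE)
  }
  structure(list(genes = do.call(rbind, gene_rows),
                 exons = do.call(rbind, exon_rows)),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene models: %d genes on %d chromosome(s)\n",
              nrow(x$genes), length(unique(x$genes$chromosome))))
  invisible(x)
}

#' Exon/intron structure of a single transcript
#'
#' Introns are the gaps between consecutive genomic-sorted exons; a
#' transcript with n exons always has n - 1 introns.
#'
#' @param exons data frame with `start` and `end` (1-based closed) of one
#'   transcript's exons.
#' @return list with sorted `exons`, `introns` (possibly empty data
#'   frame), `n_exons`, `n_introns`, `exon_lengths`, `intron_lengths`.
#' @export
exon_intron_structure <- function(exons) {
  if (nrow(exons) < 1) stop("need at least one exon")
  ex <- exons[order(exons$start), , drop = FALSE]
  if (any(ex$end < ex$start)) stop("exon with end < start")
  if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
    stop("data error: overlapping exons")
  }
  n <- nrow(ex)
  introns <- if (n > 1) {
    data.frame(start = ex$end[-n] + 1L, end = ex$start[-1] - 1L)
  } else {
    data.frame(start = integer(0), end = integer(0))
  }
  list(exons = ex, introns = introns, n_exons = n, n_introns = n - 1L,
       exon_lengths = ex$end - ex$start + 1L,
       intron_lengths = if (n > 1) introns$end - introns$start + 1L
       else integer(0))
}

#' Per-gene exon/intron summary table
#'
#' @param models a `gene_models` object from [parse_gff3()].
#' @return data frame: gene, chromosome, strand, n_exons, n_introns,
#'   exon_lengths and intron_lengths (comma-joined, genomic order).
#' @export
gene_structure_table <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  rows <- lapply(seq_len(nrow(models$genes)), function(i) {
    g <- models$genes[i, ]
    st <- exon_intron_structure(
      models$exons[models$exons$gene == g$gene, , drop = FALSE])
    data.frame(gene = g$gene, chromosome = g$chromosome,
               strand = g$strand, n_exons = st$n_exons,
               n_introns = st$n_introns,
               exon_lengths = paste(st$exon_lengths, collapse = ","),
               intron_lengths = paste(st$intron_lengths, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Chromosome distribution of genes and terminal density
#'
#' Counts genes per chromosome and the fraction of genes whose midpoint
#' lies within the terminal `terminal_fraction` at either chromosome end
#' (family members of large plant TF families tend to crowd chromosome
#' ends, so this statistic quantifies the claim).
#'
#' @param models a `gene_models` object.
#' @param chromosome_lengths named numeric vector of chromosome lengths.
#' @param terminal_fraction fraction of each chromosome counted as an end
#'   region (default 0.25 per end).
#' @return list with `counts` (named per chromosome), `terminal_density`,
#'   `positions` (data frame gene, chromosome, midpoint, relative
#'   position, terminal flag).
#' @export
chromosome_distribution <- function(models, chromosome_lengths,
                                    terminal_fraction = 0.25) {
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes
  unknown <- setdiff(unique(g$chromosome), names(chromosome_lengths))
  if (length(unknown)) {
    stop("data error: unknown chromosome length for ",
         paste(unknown, collapse = ", "))
  }
  mid <- (g$start + g$end) / 2
  rel <- mid / chromosome_lengths[g$chromosome]
  terminal <- rel <= terminal_fraction | rel >= 1 - terminal_fraction
  counts <- table(factor(g$chromosome, levels = names(chromosome_lengths)))
  list(counts = stats::setNames(as.integer(counts),
                                names(chromosome_lengths)),
       terminal_density = mean(terminal),
       positions = data.frame(gene = g$gene, chromosome = g$chromosome,
                              midpoint = mid, relative = unname(rel),
                              terminal = unname(terminal),
                              stringsAsFactors = FALSE))
}

#' Write a simple linear chromosome-map SVG
#'
#' @param distribution result of [chromosome_distribution()].
#' @param chromosome_lengths named numeric vector.
#' @param path output SVG path.
#' @return the path, invisibly.
#' @export
write_chromosome_svg <- function(distribution, chromosome_lengths, path) {
  chroms <- names(chromosome_lengths)
  width <- 600; rowh <- 40
  maxlen <- max(chromosome_lengths)
  lines <- sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
    width + 100, rowh * length(chroms) + 20)
  for (i in seq_along(chroms)) {
    y <- (i - 1) * rowh + 20
    w <- chromosome_lengths[[chroms[i]]] / maxlen * width
    lines <- c(lines,
      sprintf('<text x="5" y="%d" font-size="12">%s (n=%d)</text>',
              y + 12, chroms[i], distribution$counts[[chroms[i]]]),
      sprintf('<rect x="90" y="%d" width="%.1f" height="10" fill="#ddd" stroke="#333"/>',
              y + 4, w))
    pos <- distribution$positions
    pos <- pos[pos$chromosome == chroms[i], , drop = FALSE]
    for (p in pos$midpoint) {
      x <- 90 + p / maxlen * width
      lines <- c(lines, sprintf(
        '<line x1="%.1f" y1="%d" x2="%.1f" y2="%d" stroke="#c33"/>',
        x, y + 2, x, y + 16))
    }
  }
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}
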