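# MEME-style motif discovery under the ZOOPS model (zero or one occurrence
# per sequence): expectation-maximization on the occurrence posteriors,
# iterative discovery with masking, information-content logos, and
# per-protein motif-architecture strings.

# Convert sequences to integer index vectors once.
encode_seqs <- function(seqs) {
  lapply(strsplit(seqs, ""), function(ch) {
    idx <- match(ch, AA_ALPHABET20)
    if (anyNA(idx)) stop("non-standard residue in motif input")
    idx
  })
}

#' ZOOPS expectation-maximization for one motif
#'
#' Fits a width-`W` position frequency matrix `theta` and per-sequence
#' occurrence prior `lambda` by EM under the ZOOPS likelihood: each
#' sequence carries zero or one motif occurrence, with a uniform positional
#' prior over the `L - W + 1` possible starts. The E-step computes
#' per-position occurrence posteriors; the M-step re-estimates `theta`
#' (with a pseudocount of `0.01 x background`) and `lambda`. Because the
#' pseudocount makes the M-step a MAP update, the monotone EM objective is
#' the penalized log-likelihood (log-likelihood plus the Dirichlet
#' log-prior of `theta`); that is what `loglik_trace` records, and it is
#' non-decreasing within each run. The best of `n_starts` seeded restarts
#' by final objective is returned.
#'
#' @param seqs named character vector (all sequences must be >= `W` long).
#' @param W motif width (residues).
#' @param n_starts seeded random restarts (>= 1).
#' @param max_iter maximal EM iterations per start.
#' @param tol convergence threshold on the log-likelihood improvement.
#' @param seed integer seed.
#' @param mask optional list of logical vectors (TRUE = position masked by
#'   a previously discovered motif); windows touching masked positions get
#'   zero posterior, which guarantees motifs never overlap.
#' @param init_theta optional W x 20 row-stochastic matrix; when given, a
#'   single EM run starts from it instead of the seeded restarts.
#' @return object of class `motif_model`: `width`, `theta` (W x 20
#'   row-stochastic), `background`, `lambda`, `loglik` (final),
#'   `loglik_trace`, `occurrences` (data frame id, start, posterior; one
#'   row per sequence whose occurrence posterior exceeds 0.5), `consensus`.
#' @export
zoops_em <- function(seqs, W, n_starts = 3L, max_iter = 100L, tol = 1e-4,
                     seed = 1L, mask = NULL, init_theta = NULL) {
  if (any(nchar(seqs) < W)) {
    stop("every sequence must be at least W residues long")
  }
  if (n_starts < 1) stop("n_starts must be >= 1")
  enc <- encode_seqs(seqs)
  n <- length(enc)
  background <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET20)
  pc <- 0.01 * background
  if (is.null(mask)) mask <- lapply(enc, function(x) rep(FALSE, length(x)))
  # windows that touch a masked position are excluded from the posterior
  allowed <- lapply(seq_len(n), function(i) {
    L <- length(enc[[i]]); m <- L - W + 1L
    ok <- rep(TRUE, m)
    if (any(mask[[i]])) {
      bad <- which(mask[[i]])
      for (b in bad) ok[max(1L, b - W + 1L):min(m, b)] <- FALSE
    }
    ok
  })

  run_once <- function(theta, lambda, iters = max_iter) {
    trace <- numeric(0)
    ll_old <- -Inf
    occ <- NULL
    for (it in seq_len(iters)) {
      log_ratio <- log(theta / matrix(background, W, 20, byrow = TRUE))
      ll <- 0
      counts <- matrix(0, W, 20)
      lam_sum <- 0
      occ_rows <- vector("list", n)
      for (i in seq_len(n)) {
        x <- enc[[i]]
        m <- length(x) - W + 1L
        S <- prefix_score_matrix(x, log_ratio)[seq_len(m), W]
        S[!allowed[[i]]] <- -Inf
        # posterior over {no occurrence, start j}
        lw <- c(log(1 - lambda), log(lambda / m) + S)
        mx <- max(lw)
        wgt <- exp(lw - mx)
        z <- wgt / sum(wgt)
        ll <- ll + mx + log(sum(wgt))   # + constant log P_bg(seq)
        zocc <- z[-1]
        lam_sum <- lam_sum + sum(zocc)
        # accumulate expected residue counts over windows
        nz <- which(zocc > 1e-12)
        for (j in nz) {
          idx <- cbind(seq_len(W), x[j:(j + W - 1L)])
          counts[idx] <- counts[idx] + zocc[j]
        }
        if (sum(zocc) > 0.5) {
          jbest <- which.max(zocc)
          occ_rows[[i]] <- data.frame(id = names(seqs)[i], start = jbest,
                                      posterior = sum(zocc),
                                      stringsAsFactors = FALSE)
        }
      }
      # penalized (MAP) objective: likelihood plus Dirichlet prior term
      trace <- c(trace, ll + sum(log(theta) *
                                   matrix(pc, W, 20, byrow = TRUE)))
      ll <- trace[length(trace)]
      theta <- sweep(counts + matrix(pc, W, 20, byrow = TRUE), 1,
                     rowSums(counts) + sum(pc), "/")
      lambda <- min(max(lam_sum / n, 1e-9), 1 - 1e-9)
      occ <- do.call(rbind, occ_rows)
      if (ll - ll_old < tol && it > 1) break
      ll_old <- ll
    }
    colnames(theta) <- AA_ALPHABET20
    list(theta = theta, lambda = lambda, loglik = trace[length(trace)],
         trace = trace, occurrences = occ)
  }

  theta_from_window <- function(i, j) {
    win <- enc[[i]][j:(j + W - 1L)]
    th <- matrix((1 - 0.5) / 19, W, 20)
    th[cbind(seq_len(W), win)] <- 0.5
    th
  }
  if (!is.null(init_theta)) {
    stopifnot(nrow(init_theta) == W, ncol(init_theta) == 20)
    best <- run_once(init_theta, lambda = 0.5)
  } else {
    # MEME-style seeding: score a pool of candidate windows with a short
    # EM burst and run full EM only from the most promising ones
    n_cand <- max(8L, 4L * n_starts)
    cands <- with_seed(derive_seed(seed, "zoops_candidates"), {
      lapply(seq_len(n_cand), function(s) {
        repeat {
          i <- sample.int(n, 1L)
          ok <- which(allowed[[i]])
          if (length(ok)) return(c(i, ok[sample.int(length(ok), 1L)]))
        }
      })
    })
    burst <- vapply(cands, function(cj) {
      run_once(theta_from_window(cj[1], cj[2]), lambda = 0.5,
               iters = 2L)$loglik
    }, numeric(1))
    top <- order(burst, decreasing = TRUE)[seq_len(min(n_starts, n_cand))]
    best <- NULL
    for (s in top) {
      fit <- run_once(theta_from_window(cands[[s]][1], cands[[s]][2]),
                      lambda = 0.5)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  }
  if (is.null(best$occurrences)) {
    best$occurrences <- data.frame(id = character(0), start = integer(0),
                                   posterior = numeric(0))
  }
  consensus <- paste(AA_ALPHABET20[apply(best$theta, 1, which.max)],
                     collapse = "")
  structure(list(width = W, theta = best$theta, background = background,
                 lambda = best$lambda, loglik = best$loglik,
                 loglik_trace = best$trace,
                 occurrences = best$occurrences, consensus = consensus),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("ZOOPS motif: width %d, lambda %.3f, consensus %s\n",
              x$width, x$lambda, x$consensus))
  invisible(x)
}

# Relative entropy (bits) of each motif column vs background.
relative_entropy_cols <- function(theta, background) {
  rowSums(theta * log2(sweep(theta, 2, background, "/")), na.rm = TRUE)
}

# Mean relative entropy (bits) per motif column vs background.
relative_entropy_per_col <- function(theta, background) {
  mean(relative_entropy_cols(theta, background))
}

# Expected relative entropy of a pure-background column estimated from
# n_eff sites (first-order small-sample bias of the plug-in estimator).
re_small_sample_bias <- function(n_eff) {
  19 / (2 * log(2) * max(n_eff, 1))
}

# Drop flanking motif columns whose relative entropy stays below the trim
# threshold; shifts occurrence starts accordingly.
trim_motif <- function(fit, trim_ic) {
  re <- relative_entropy_cols(fit$theta, fit$background)
  keep <- which(re >= trim_ic)
  if (!length(keep)) return(NULL)
  lo <- min(keep); hi <- max(keep)
  if (lo == 1 && hi == fit$width) return(fit)
  fit$theta <- fit$theta[lo:hi, , drop = FALSE]
  fit$width <- hi - lo + 1L
  if (nrow(fit$occurrences)) fit$occurrences$start <-
      fit$occurrences$start + lo - 1L
  fit$consensus <- paste(AA_ALPHABET20[apply(fit$theta, 1, which.max)],
                         collapse = "")
  fit
}

#' Discover multiple motifs by iterated ZOOPS-EM with masking
#'
#' Repeats: pick the motif width maximizing the bias-corrected total
#' relative entropy over a width grid (small-sample bias makes raw
#' relative entropy of background columns look informative, so each
#' column's expected background value is subtracted; among widths within
#' 2 percent of the maximum the largest is preferred), fit by [zoops_em()],
#' trim flanking columns whose relative entropy stays below `trim_ic`
#' (so an over-wide window shrinks to the informative core), mask the
#' occurrences (windows overlapping any previous occurrence are excluded
#' from later posteriors), and continue until `max_motifs` motifs are
#' found or the best motif's corrected relative entropy per column falls
#' below `min_re` bits. Motifs are numbered by discovery order.
#'
#' @param seqs named character vector of protein sequences.
#' @param max_motifs maximum number of motifs (the customary cap is 15).
#' @param width_grid candidate widths; the default covers 6-50 in steps of
#'   3 with local refinement, a practical window within the nominal 2-250
#'   bound (EM at very large widths is degenerate on short proteins).
#' @param min_re stopping threshold, bits of corrected relative entropy
#'   per column.
#' @param trim_ic flank-trimming threshold in bits (default: twice the
#'   small-sample bias, floored at 0.5).
#' @param n_starts,max_iter,tol,seed passed to [zoops_em()].
#' @return list of `motif_model` objects (discovery order), each with an
#'   `id` element; occurrences across motifs never overlap.
#' @export
discover_motifs <- function(seqs, max_motifs = 15L,
                            width_grid = seq(6L, 50L, by = 3L),
                            min_re = 0.3, trim_ic = NULL, n_starts = 2L,
                            max_iter = 50L, tol = 1e-4, seed = 1L) {
  if (length(seqs) == 0) stop("empty sequence set")
  motifs <- list()
  mask <- lapply(strsplit(seqs, ""), function(ch) rep(FALSE, length(ch)))
  for (t in seq_len(max_motifs)) {
    usable <- nchar(seqs)
    grid <- width_grid[width_grid <= min(usable)]
    if (!length(grid)) break
    score_width <- function(w) {
      fit <- zoops_em(seqs, w, n_starts = 1L, max_iter = 15L, tol = tol,
                      seed = derive_seed(seed, sprintf("w%d_m%d", w, t)),
                      mask = mask)
      n_eff <- fit$lambda * length(seqs)
      re <- relative_entropy_cols(fit$theta, fit$background)
      sum(re - re_small_sample_bias(n_eff))
    }
    scores <- vapply(grid, score_width, numeric(1))
    best <- max(scores)
    # prefer the widest window near the optimum; trimming recovers the core
    w_best <- max(grid[scores >= best - 0.02 * abs(best)])
    fit <- zoops_em(seqs, w_best, n_starts = n_starts, max_iter = max_iter,
                    tol = tol,
                    seed = derive_seed(seed, sprintf("final_m%d", t)),
                    mask = mask)
    n_eff <- fit$lambda * length(seqs)
    bias <- re_small_sample_bias(n_eff)
    thr <- if (is.null(trim_ic)) max(2 * bias, 0.5) else trim_ic
    w_before <- fit$width
    fit <- trim_motif(fit, thr)
    if (is.null(fit)) break
    if (fit$width < w_before) {
      # refit at the informative core width so occurrences the over-wide
      # window could not align (sites too close to a sequence end) are
      # recovered
      fit <- zoops_em(seqs, fit$width, max_iter = max_iter, tol = tol,
                      mask = mask, init_theta = fit$theta)
      fit <- trim_motif(fit, thr)
      if (is.null(fit)) break
    }
    # widen-and-retrim refinement: the trimmed window may sit on a
    # truncated registration of the true motif; pad the model with
    # background columns, let EM re-align, trim again, and keep the wider
    # model when its bias-corrected information total improves
    corrected_total <- function(f) {
      sum(relative_entropy_cols(f$theta, f$background) -
            re_small_sample_bias(f$lambda * length(seqs)))
    }
    for (round in 1:3) {
      pad <- 6L
      w_new <- fit$width + 2L * pad
      if (w_new > min(nchar(seqs))) break
      init <- rbind(matrix(1 / 20, pad, 20), fit$theta,
                    matrix(1 / 20, pad, 20))
      wide <- zoops_em(seqs, w_new, max_iter = max_iter, tol = tol,
                       mask = mask, init_theta = init)
      # EM picks the registration that flatters the padding, so newly
      # exposed flank columns face a stricter trim threshold
      thr_wide <- max(3 * re_small_sample_bias(wide$lambda * length(seqs)),
                      0.75)
      wide <- trim_motif(wide, thr_wide)
      if (is.null(wide) || wide$width <= fit$width ||
          corrected_total(wide) <= corrected_total(fit)) break
      wide <- zoops_em(seqs, wide$width, max_iter = max_iter, tol = tol,
                       mask = mask, init_theta = wide$theta)
      wide <- trim_motif(wide, thr)
      if (is.null(wide)) break
      fit <- wide
    }
    if (nrow(fit$occurrences) == 0) break
    re <- relative_entropy_per_col(fit$theta, fit$background) - bias
    if (re < min_re) break
    fit$id <- t
    fit$re_per_col <- re
    motifs[[t]] <- fit
    for (r in seq_len(nrow(fit$occurrences))) {
      i <- match(fit$occurrences$id[r], names(seqs))
      s <- fit$occurrences$start[r]
      mask[[i]][s:(s + fit$width - 1L)] <- TRUE
    }
  }
  motifs
}

#' Per-column information content and logo letter heights
#'
#' `IC_j = log2(20) - H(theta_j)` with Shannon entropy `H` in bits (no
#' small-sample correction); letter heights are `frequency x IC`, so the
#' stack height of a logo column equals its information content.
#'
#' @param theta row-stochastic position frequency matrix (W x 20).
#' @return list with `ic` (bits per column) and `heights` (W x 20 matrix).
#' @export
information_content <- function(theta) {
  if (any(theta < 0) || any(abs(rowSums(theta) - 1) > 1e-6)) {
    stop("theta rows must be non-negative and sum to 1")
  }
  H <- -rowSums(ifelse(theta > 0, theta * log2(theta), 0))
  ic <- log2(20) - H
  heights <- sweep(theta, 1, ic, "*")
  list(ic = ic, heights = heights)
}

#' Ordered motif-architecture strings per protein
#'
#' @param motifs list of `motif_model`s from [discover_motifs()].
#' @param ids optional protein ids to report (default: all with >= 1
#'   occurrence).
#' @return data frame `id`, `architecture` (motif ids joined by `-` in
#'   start order).
#' @export
motif_architectures <- function(motifs, ids = NULL) {
  occ <- do.call(rbind, lapply(motifs, function(m) {
    if (nrow(m$occurrences) == 0) return(NULL)
    cbind(m$occurrences, motif = m$id)
  }))
  if (is.null(occ)) {
    return(data.frame(id = character(0), architecture = character(0)))
  }
  if (is.null(ids)) ids <- unique(occ$id)
  arch <- vapply(ids, function(p) {
    sub <- occ[occ$id == p, , drop = FALSE]
    if (nrow(sub) == 0) return("")
    paste(sub$motif[order(sub$start)], collapse = "-")
  }, character(1))
  data.frame(id = ids, architecture = unname(arch),
             stringsAsFactors = FALSE)
}

#' Within-group conservation of motif architectures
#'
#' @param architectures data frame from [motif_architectures()].
#' @param group_map named character vector protein id -> group.
#' @return data frame per group: `group`, `n`, `modal_architecture`,
#'   `conserved_fraction` (members matching the modal string).
#' @export
architecture_conservation <- function(architectures, group_map) {
  missing <- setdiff(architectures$id, names(group_map))
  if (length(missing)) {
    stop("proteins without a group: ", paste(missing, collapse = ", "))
  }
  groups <- unique(group_map[architectures$id])
  rows <- lapply(groups, function(g) {
    ids <- architectures$id[group_map[architectures$id] == g]
    a <- architectures$architecture[architectures$id %in% ids]
    if (!length(a)) {
      warning("group ", g, " has no members with architectures; skipped")
      return(NULL)
    }
    tab <- sort(table(a), decreasing = TRUE)
    data.frame(group = g, n = length(a), modal_architecture = names(tab)[1],
               conserved_fraction = as.numeric(tab[1]) / length(a),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write motifs in MEME minimal text format
#'
#' @param motifs list of `motif_model`s.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_meme_minimal <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACDEFGHIKLMNPQRSTVWY", "",
               "Background letter frequencies", paste(
                 paste(sort(AA_ALPHABET20),
                       format_num(rep(1 / 20, 20), 4)), collapse = " "),
               ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF motif_%d", m$id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 20 w= %d nsites= %d",
      m$width, nrow(m$occurrences)), con)
    th <- m$theta[, sort(AA_ALPHABET20), drop = FALSE]
    for (j in seq_len(m$width)) {
      writeLines(paste(format_num(th[j, ], 6), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Write a simple SVG sequence logo for a motif
#'
#' Letter heights are frequency times column information content, so each
#' stack's total height equals the column's IC in bits.
#'
#' @param motif a `motif_model`.
#' @param path output SVG path.
#' @return the path, invisibly.
#' @export
write_logo_svg <- function(motif, path) {
  icd <- information_content(motif$theta)
  W <- motif$width
  colw <- 20; maxh <- 100; maxbits <- log2(20)
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
    W * colw, maxh + 20))
  for (j in seq_len(W)) {
    h <- icd$heights[j, ]
    ord <- order(h)
    y <- maxh
    for (a in ord) {
      if (h[a] <= 0) next
      px <- h[a] / maxbits * maxh
      y <- y - px
      lines <- c(lines, sprintf(
        '<text x="%d" y="%.2f" font-family="monospace" font-size="%.2f" textLength="%d" lengthAdjust="spacingAndGlyphs">%s</text>',
        (j - 1) * colw, y + px, px * 1.1, colw - 2, AA_ALPHABET20[a]))
    }
    lines <- c(lines, sprintf(
      '<text x="%d" y="%d" font-size="8">%d</text>',
      (j - 1) * colw + 5, maxh + 12, j))
  }
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}
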