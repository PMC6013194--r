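# Relative expression from qPCR Ct tables with the Livak 2^-ddCt model:
# per-replicate normalization against a reference (housekeeping) gene,
# fold change against a calibrator condition, and qualitative trend calls
# across developmental stages. Amplification efficiency is fixed at 2 (the
# Livak assumption).

#' Per-replicate delta-Ct against the reference gene
#'
#' `dCt = Ct_target - Ct_reference`, paired within each (cultivar, stage,
#' replicate). A replicate without its reference measurement is a data
#' error naming the condition.
#'
#' @param records data frame with columns `gene`, `cultivar`,
#'   `stage_DAFB`, `replicate`, `Ct`.
#' @param reference_gene housekeeping gene name present in `records`.
#' @return data frame `gene`, `cultivar`, `stage_DAFB`, `replicate`,
#'   `delta_ct`.
#' @export
delta_ct <- function(records, reference_gene) {
  req <- c("gene", "cultivar", "stage_DAFB", "replicate", "Ct")
  stopifnot(all(req %in% names(records)))
  if (!reference_gene %in% records$gene) {
    stop("reference gene ", reference_gene, " absent from the Ct table")
  }
  out_of_range <- records$Ct < 10 | records$Ct > 40
  if (any(out_of_range)) {
    warning(sum(out_of_range), " Ct value(s) outside the typical 10-40 ",
            "cycle range")
  }
  ref <- records[records$gene == reference_gene, , drop = FALSE]
  # the reference gene itself is kept as a target (its dCt is 0 by
  # construction), which downstream yields fold 1 everywhere
  tgt <- records
  key <- function(d) paste(d$cultivar, d$stage_DAFB, d$replicate, sep = "\r")
  ref_ct <- stats::setNames(ref$Ct, key(ref))
  k <- key(tgt)
  missing <- !(k %in% names(ref_ct))
  if (any(missing)) {
    cond <- unique(tgt[missing, c("cultivar", "stage_DAFB", "replicate")])
    stop("data error: missing reference Ct for condition(s): ",
         paste(apply(cond, 1, paste, collapse = "/"), collapse = "; "))
  }
  data.frame(gene = tgt$gene, cultivar = tgt$cultivar,
             stage_DAFB = tgt$stage_DAFB, replicate = tgt$replicate,
             delta_ct = tgt$Ct - unname(ref_ct[k]),
             stringsAsFactors = FALSE)
}

#' 2^-ddCt fold changes against a calibrator condition
#'
#' `ddCt = mean dCt(condition) - mean dCt(calibrator)`; fold =
#' `2^-ddCt`. The standard error of ddCt combines the replicate standard
#' errors of both conditions; it is propagated through `2^-x` (delta
#' method) and also reported as the fold range
#' `[2^-(ddCt + SE), 2^-(ddCt - SE)]`.
#'
#' @param dct result of [delta_ct()].
#' @param calibrator `"first_stage"` (default: the earliest stage of the
#'   same gene within the same cultivar) or a data frame with columns
#'   `gene`, `cultivar`, `stage_DAFB` naming the calibrator condition per
#'   gene and cultivar.
#' @return data frame per (gene, cultivar, stage): `delta_ct_mean`,
#'   `ddct`, `fold`, `fold_se`, `fold_lo`, `fold_hi`, `is_calibrator`.
#' @export
ddct_fold <- function(dct, calibrator = "first_stage") {
  agg <- stats::aggregate(delta_ct ~ gene + cultivar + stage_DAFB, dct,
                          function(x) c(mean = mean(x),
                                        se = stats::sd(x) / sqrt(length(x))))
  agg <- cbind(agg[c("gene", "cultivar", "stage_DAFB")],
               as.data.frame(agg$delta_ct))
  agg$se[is.na(agg$se)] <- 0
  rows <- list()
  for (g in unique(agg$gene)) {
    for (cv in unique(agg$cultivar[agg$gene == g])) {
      sub <- agg[agg$gene == g & agg$cultivar == cv, , drop = FALSE]
      sub <- sub[order(sub$stage_DAFB), , drop = FALSE]
      if (identical(calibrator, "first_stage")) {
        cal_stage <- sub$stage_DAFB[1]
      } else {
        hit <- calibrator[calibrator$gene == g &
                            calibrator$cultivar == cv, , drop = FALSE]
        if (nrow(hit) != 1) {
          stop("calibrator condition absent for ", g, "/", cv)
        }
        cal_stage <- hit$stage_DAFB
        if (!cal_stage %in% sub$stage_DAFB) {
          stop("calibrator stage ", cal_stage, " has no dCt values for ",
               g, "/", cv)
        }
      }
      cal <- sub[sub$stage_DAFB == cal_stage, , drop = FALSE]
      ddct <- sub$mean - cal$mean
      se <- sqrt(sub$se ^ 2 + cal$se ^ 2)
      se[sub$stage_DAFB == cal_stage] <- 0
      fold <- 2 ^ (-ddct)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, cultivar = cv, stage_DAFB = sub$stage_DAFB,
        delta_ct_mean = sub$mean, ddct = ddct, fold = fold,
        fold_se = fold * log(2) * se,
        fold_lo = 2 ^ (-(ddct + se)), fold_hi = 2 ^ (-(ddct - se)),
        is_calibrator = sub$stage_DAFB == cal_stage,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Qualitative temporal trend of a fold-change series
#'
#' `"decreasing"` when every successive ratio stays at or below
#' `1 + tolerance` and the last value is below the first; `"increasing"`
#' symmetrically; otherwise `"none"`.
#'
#' @param folds numeric fold changes ordered by stage (>= 3 stages).
#' @param tolerance allowed counter-movement per step (default 0.05).
#' @return one of `"decreasing"`, `"increasing"`, `"none"`.
#' @export
trend_call <- function(folds, tolerance = 0.05) {
  if (length(folds) < 3) stop("need at least 3 stages for a trend call")
  ratio <- folds[-1] / folds[-length(folds)]
  overall <- folds[length(folds)] / folds[1]
  if (all(ratio <= 1 + tolerance) && overall < 1) return("decreasing")
  if (all(ratio >= 1 / (1 + tolerance)) && overall > 1) return("increasing")
  "none"
}

#' Full relative-expression analysis of a Ct table
#'
#' @param records Ct data frame (or path to a TSV with the same columns).
#' @param reference_gene housekeeping gene.
#' @param calibrator see [ddct_fold()].
#' @param tolerance see [trend_call()].
#' @return object of class `expression_result`: `folds` (per condition)
#'   and `trends` (per gene and cultivar).
#' @export
relative_expression <- function(records, reference_gene = "RPII",
                                calibrator = "first_stage",
                                tolerance = 0.05) {
  if (is.character(records) && length(records) == 1) {
    records <- utils::read.delim(records, stringsAsFactors = FALSE)
  }
  folds <- ddct_fold(delta_ct(records, reference_gene), calibrator)
  trows <- list()
  for (g in unique(folds$gene)) {
    for (cv in unique(folds$cultivar[folds$gene == g])) {
      sub <- folds[folds$gene == g & folds$cultivar == cv, , drop = FALSE]
      sub <- sub[order(sub$stage_DAFB), , drop = FALSE]
      tr <- if (nrow(sub) >= 3) trend_call(sub$fold, tolerance) else
        NA_character_
      trows[[length(trows) + 1L]] <- data.frame(
        gene = g, cultivar = cv, trend = tr, stringsAsFactors = FALSE)
    }
  }
  structure(list(folds = folds, trends = do.call(rbind, trows)),
            class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("relative expression: %d genes x %d cultivars, %d stages\n",
              length(unique(x$folds$gene)),
              length(unique(x$folds$cultivar)),
              length(unique(x$folds$stage_DAFB))))
  tab <- table(x$trends$trend, useNA = "no")
  cat("  trends:", paste(sprintf("%s=%d", names(tab), tab),
                         collapse = ", "), "\n")
  invisible(x)
}
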