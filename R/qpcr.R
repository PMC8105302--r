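#' Delta-delta-Ct relative quantification
#'
#' Classic ddCt with amplification efficiency 2:
#' `dCt_pop = Ct_target - Ct_housekeeping` within each population,
#' `rel_expr_pop = 2^(-dCt_pop)`, and
#' `fold_enrichment = 2^-(dCt_pos - dCt_neg)` (positive vs reference
#' population). Undetected targets get relative expression 0 and are
#' excluded from fold ranking.
#'
#' @param ct data.frame with columns gene_id, ct_target_pos,
#'   ct_target_neg, ct_housekeeping_pos, ct_housekeeping_neg and optional
#'   logical `detected` (default TRUE).
#' @return data.frame: gene_id, dct_pos, dct_neg, ddct, rel_expr_pos,
#'   rel_expr_neg, fold_enrichment, detected.
#' @export
ddct_relative_expression <- function(ct) {
  req <- c("gene_id", "ct_target_pos", "ct_target_neg",
           "ct_housekeeping_pos", "ct_housekeeping_neg")
  stopifnot(all(req %in% names(ct)))
  if (anyNA(ct$ct_housekeeping_pos) || anyNA(ct$ct_housekeeping_neg)) {
    stop("missing housekeeping Ct")
  }
  det <- if ("detected" %in% names(ct)) ct$detected else rep(TRUE, nrow(ct))
  dpos <- ct$ct_target_pos - ct$ct_housekeeping_pos
  dneg <- ct$ct_target_neg - ct$ct_housekeeping_neg
  ddct <- dpos - dneg
  out <- data.frame(gene_id = ct$gene_id, dct_pos = dpos, dct_neg = dneg,
                    ddct = ddct,
                    rel_expr_pos = 2^(-dpos), rel_expr_neg = 2^(-dneg),
                    fold_enrichment = 2^(-ddct),
                    detected = det, stringsAsFactors = FALSE)
  out$rel_expr_pos[!det] <- 0
  out$fold_enrichment[!det] <- NA_real_
  out
}

#' Positive-vs-negative enrichment scatter table
#'
#' One row per gene with the two relative expressions as scatter axes
#' (reference population on x, positive population on y) and a flag
#' marking the `label_top` genes by fold enrichment for annotation. Ties
#' at the cutoff are all flagged. Undetected genes are never flagged.
#'
#' @param rel table from [ddct_relative_expression()].
#' @param label_top how many top genes to flag (default 5).
#' @param log10_axes add log10-transformed axis columns.
#' @return data.frame: gene_id, x = rel_expr_neg, y = rel_expr_pos,
#'   fold_enrichment, annotate (+ log10_x/log10_y if requested).
#' @export
enrichment_scatter_table <- function(rel, label_top = 5, log10_axes = FALSE) {
  if (nrow(rel) == 0) stop("empty relative-expression table")
  out <- data.frame(gene_id = rel$gene_id,
                    x = rel$rel_expr_neg, y = rel$rel_expr_pos,
                    fold_enrichment = rel$fold_enrichment,
                    stringsAsFactors = FALSE)
  folds <- out$fold_enrichment
  folds[!rel$detected] <- NA
  ok <- !is.na(folds)
  ann <- rep(FALSE, nrow(out))
  if (label_top >= 1 && any(ok)) {
    srt <- sort(folds[ok], decreasing = TRUE)
    cut <- srt[min(label_top, length(srt))]
    ann[ok] <- folds[ok] >= cut   # ties at the cutoff: flag all
  }
  out$annotate <- ann
  if (log10_axes) {
    out$log10_x <- log10(out$x)
    out$log10_y <- log10(out$y)
  }
  out
}
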