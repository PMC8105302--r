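#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with enforced monotonicity, capped at 1 (delegates to
#' [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length/order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select differentially expressed genes
#'
#' Strict thresholds: `padj < padj_max` AND `|log2fc| > lfc_min`; genes
#' sitting exactly on either boundary are excluded.
#'
#' @param de DE result table from [fit_paired_nb_wald()].
#' @param padj_max adjusted-p cutoff (default 0.05).
#' @param lfc_min absolute log2 fold-change cutoff (default 1).
#' @return subset of `de` rows passing both filters.
#' @export
select_de <- function(de, padj_max = 0.05, lfc_min = 1) {
  stopifnot(all(c("padj", "log2fc") %in% names(de)))
  keep <- !is.na(de$padj) & de$padj < padj_max & abs(de$log2fc) > lfc_min
  de[keep, , drop = FALSE]
}

#' Top-k genes by log2 fold change in one direction
#'
#' Among genes with raw `p < p_max`, returns the `k` most extreme log2 fold
#' changes in the requested direction, sorted by |log2fc| descending; ties
#' broken by smaller p, then lexicographic gene id. Genes with log2fc of
#' the wrong sign (or exactly 0) are never eligible.
#'
#' @param de DE result table.
#' @param k list length (default 50).
#' @param direction `"up"` or `"down"`.
#' @param p_max raw-p eligibility cutoff (default 0.01).
#' @return eligible rows, at most `k`, in rank order; attribute `short` is
#'   TRUE (with a warning) when fewer than `k` genes were eligible.
#' @export
top_k_by_lfc <- function(de, k = 50, direction = c("up", "down"),
                         p_max = 0.01) {
  direction <- match.arg(direction)
  stopifnot(k >= 1)
  elig <- !is.na(de$p) & de$p < p_max &
    (if (direction == "up") de$log2fc > 0 else de$log2fc < 0)
  sub <- de[elig, , drop = FALSE]
  ord <- order(-abs(sub$log2fc), sub$p, sub$gene_id)
  sub <- sub[ord, , drop = FALSE]
  short <- nrow(sub) < k
  if (short) {
    warning(sprintf("only %d genes eligible for top-%d %s list",
                    nrow(sub), k, direction))
  } else {
    sub <- sub[seq_len(k), , drop = FALSE]
  }
  attr(sub, "short") <- short
  sub
}

#' log2(x+1) normalized-expression marker panel
#'
#' Heatmap-ready matrix of `log2(count / size_factor + 1)` for a marker
#' list, rows in marker order. Markers absent from the count matrix are
#' dropped with a warning (never silently).
#'
#' @param cm a [count_matrix()].
#' @param sf size factors.
#' @param marker_ids character vector of gene ids, output row order.
#' @return numeric matrix (markers x samples); attribute `missing_ids`
#'   lists requested ids not present.
#' @export
log2p1_panel <- function(cm, sf, marker_ids) {
  present <- marker_ids %in% rownames(cm$counts)
  if (any(!present)) {
    warning("marker ids not in count matrix: ",
            paste(marker_ids[!present], collapse = ", "))
  }
  ids <- marker_ids[present]
  norm <- sweep(cm$counts[ids, , drop = FALSE], 2, sf, "/")
  out <- log2(norm + 1)
  attr(out, "missing_ids") <- marker_ids[!present]
  out
}
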