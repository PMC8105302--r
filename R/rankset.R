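#' Signed gene scores from a differential-expression table
#'
#' The per-gene enrichment score is the log10-transformed DE p-value with
#' inverted sign, multiplied by the sign of the log2 fold change:
#' `s_g = -log10(max(p_g, p_floor)) * sign(log2fc_g)`. Raw p-values are
#' used by default; the floor guards against -log10 overflow for extreme
#' p-values.
#'
#' @param de DE result table (needs `gene_id`, `log2fc`, and `p` or
#'   `padj`).
#' @param use_adjusted score from BH-adjusted rather than raw p-values.
#' @param p_floor smallest p entering the log (default 1e-300).
#' @return data.frame: gene_id, score, lfc, p. Genes with missing p are
#'   dropped with a message.
#' @export
signed_scores <- function(de, use_adjusted = FALSE, p_floor = 1e-300) {
  p <- if (use_adjusted) de$padj else de$p
  if (any(p > 1, na.rm = TRUE)) stop("p-values must not exceed 1")
  drop <- is.na(p)
  if (any(drop)) {
    message(sum(drop), " gene(s) without a p-value dropped from scoring")
  }
  d <- de[!drop, , drop = FALSE]
  p <- p[!drop]
  data.frame(gene_id = d$gene_id,
             score = -log10(pmax(p, p_floor)) * sign(d$log2fc),
             lfc = d$log2fc, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Two-sided Mann-Whitney U test of scores[idx] vs scores[-idx].
# ranks/tie data are precomputed once per collection for speed.
# Exact mode (no ties, small set and universe) uses the exact U
# distribution; otherwise normal approximation with mid-ranks, tie
# correction and optional continuity correction.
mww_set_test <- function(ranks, n_total, tie_term, has_ties, idx,
                         exact_max_members = 10, exact_max_universe = 25,
                         continuity = TRUE) {
  n1 <- length(idx)
  n2 <- n_total - n1
  r1 <- sum(ranks[idx])
  u <- r1 - n1 * (n1 + 1) / 2
  exact <- !has_ties && n1 <= exact_max_members && n_total <= exact_max_universe
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n_total + 1) - tie_term)
  if (sigma2 <= 0) {  # all scores tied: the test carries no information
    return(list(u = u, z = 0, p = 1, exact = FALSE))
  }
  d <- u - mu
  cc <- if (continuity) sign(d) * 0.5 else 0
  z <- (d - cc) / sqrt(sigma2)
  if (exact) {
    p <- if (u > mu) {
      2 * stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(u, n1, n2)
    }
    p <- min(p, 1)
  } else {
    p <- min(2 * stats::pnorm(-abs(z)), 1)
  }
  list(u = u, z = z, p = p, exact = exact)
}

#' Signed-score MWW geneset enrichment over a collection
#'
#' For each geneset, a two-sided Mann-Whitney-Wilcoxon test compares the
#' mean rank of the signed scores of member genes against all other genes
#' in the scored universe. Sets are intersected with the universe first,
#' then size-filtered to `[min_size, max_size]`; the Bonferroni family size
#' M is the number of sets actually tested. Mid-ranks with tie-corrected
#' variance and (by default) continuity correction are used; for small
#' tie-free cases the exact U distribution is used instead. Volcano
#' coordinates are attached per set: x is the member log2 fold changes
#' weighted by `-log10(p_g)`, y is `-log10(p_enrich)`.
#'
#' @param scores table from [signed_scores()].
#' @param sets named list of gene-id vectors (see [read_gmt()]).
#' @param min_size,max_size inclusive set-size bounds after intersection
#'   (defaults 10 and 500).
#' @param alpha familywise error rate for the Bonferroni flag.
#' @param continuity apply continuity correction in the normal
#'   approximation.
#' @param exact_max_members,exact_max_universe bounds under which the
#'   exact U distribution is used (tie-free scores only).
#' @return data.frame: set_name, n_in, u_stat, z, p_enrich,
#'   bonferroni_significant, x_volcano, y_volcano, bubble_size, exact.
#'   Attribute `m_tests` is the Bonferroni family size.
#' @export
enrich_collection <- function(scores, sets, min_size = 10, max_size = 500,
                              alpha = 0.05, continuity = TRUE,
                              exact_max_members = 10,
                              exact_max_universe = 25) {
  if (nrow(scores) == 0) stop("empty universe: no scored genes")
  if (length(sets) == 0) stop("empty geneset collection")
  universe <- scores$gene_id
  members <- lapply(sets, function(s) unique(s[s %in% universe]))
  sz <- lengths(members)
  keep <- sz >= min_size & sz <= max_size
  if (!any(keep)) {
    stop("no geneset survives the size filter [", min_size, ", ", max_size,
         "] after intersection with the ", length(universe),
         "-gene universe")
  }
  members <- members[keep]
  m_tests <- length(members)

  ranks <- rank(scores$score)          # mid-ranks
  n_total <- length(ranks)
  ties <- table(scores$score)
  has_ties <- any(ties > 1)
  tie_term <- sum(ties^3 - ties) / (n_total * (n_total - 1))
  idx_of <- stats::setNames(seq_len(n_total), universe)
  w_all <- -log10(pmax(scores$p, 1e-300))

  rows <- lapply(names(members), function(nm) {
    idx <- idx_of[members[[nm]]]
    tst <- mww_set_test(ranks, n_total, tie_term, has_ties, idx,
                        exact_max_members, exact_max_universe, continuity)
    wsum <- sum(w_all[idx])
    x <- if (wsum > 0) sum(w_all[idx] * scores$lfc[idx]) / wsum else NA_real_
    data.frame(set_name = nm, n_in = length(idx), u_stat = tst$u, z = tst$z,
               p_enrich = tst$p,
               bonferroni_significant = tst$p < alpha / m_tests,
               x_volcano = x, y_volcano = -log10(tst$p),
               bubble_size = length(idx), exact = tst$exact,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$x_volcano)) {
    warning("x_volcano missing for set(s) with all member p-values = 1: ",
            paste(out$set_name[is.na(out$x_volcano)], collapse = ", "))
  }
  rownames(out) <- NULL
  attr(out, "m_tests") <- m_tests
  out
}

#' Volcano coordinates for one geneset
#'
#' x is the weighted mean of the member genes' log2 fold changes, each gene
#' weighted by `-log10(p_g)`; y is `-log10(p_enrich)` of the set.
#'
#' @param scores table from [signed_scores()].
#' @param p_enrich the set's enrichment p-value.
#' @param members gene ids of the set (must be scored).
#' @return list with `x` and `y`; `x` is NA (with a warning) when every
#'   member weight is zero (all member p = 1).
#' @export
volcano_coordinates <- function(scores, p_enrich, members) {
  if (!all(members %in% scores$gene_id)) {
    stop("all members must be in the scored universe")
  }
  i <- match(members, scores$gene_id)
  w <- -log10(pmax(scores$p[i], 1e-300))
  if (sum(w) <= 0) {
    warning("all member weights are zero (p = 1); x is missing")
    x <- NA_real_
  } else {
    x <- sum(w * scores$lfc[i]) / sum(w)
  }
  list(x = x, y = -log10(p_enrich))
}

#' Geneset-enrichment volcano plot
#'
#' Bubble scatter of the enrichment table: weighted mean log2 fold change
#' on x, `-log10(p_enrich)` on y, bubble area proportional to set size,
#' with the Bonferroni threshold as a dotted horizontal line. Downregulated
#' sets (x < 0) are green, upregulated red.
#'
#' @param enr table from [enrich_collection()].
#' @param alpha familywise error rate used for the threshold line.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `enr`.
#' @export
plot_volcano <- function(enr, alpha = 0.05, ...) {
  m <- attr(enr, "m_tests")
  if (is.null(m)) m <- nrow(enr)
  col <- ifelse(enr$x_volcano < 0, "forestgreen", "firebrick")
  cex <- 0.5 + 2 * sqrt(enr$bubble_size / max(enr$bubble_size))
  graphics::plot(enr$x_volcano, enr$y_volcano, col = col, cex = cex,
                 pch = 16, xlab = "weighted mean log2 fold change",
                 ylab = "-log10 enrichment p", ...)
  graphics::abline(h = -log10(alpha / m), lty = 3)
  invisible(enr)
}
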