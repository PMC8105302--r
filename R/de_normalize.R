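#' Median-of-ratios size factors
#'
#' For each sample j, s_j is the median over reference genes (genes with
#' strictly positive counts in every sample) of K_gj / geomean_g(K_g.),
#' then the vector is rescaled to geometric mean 1 so that normalized
#' counts stay on the raw-count scale.
#'
#' @param cm a [count_matrix()].
#' @return named numeric vector of positive size factors (geometric mean 1).
#' @export
size_factors <- function(cm) {
  k <- cm$counts
  ref <- rowSums(k > 0) == ncol(k)
  if (!any(ref)) {
    stop("cannot estimate size factors: no gene has strictly positive ",
         "counts in all samples")
  }
  logk <- log(k[ref, , drop = FALSE])
  loggeo <- rowMeans(logk)
  s <- apply(logk, 2, function(col) exp(stats::median(col - loggeo)))
  s <- s / exp(mean(log(s)))
  s
}

#' Per-gene method-of-moments NB dispersion
#'
#' On size-factor-normalized counts, within each population group with a
#' positive mean, alpha_group = max(0, (s^2 - mean) / mean^2); the gene's
#' dispersion is the average over groups, floored at `alpha_min`. Genes
#' with zero mean in every group get `alpha_min` and are flagged.
#'
#' With `method = "design"` the dispersion is instead estimated from
#' residuals around design-fitted means (log-linear least-squares fit of
#' `~ mouse + population` on shifted normalized counts), the
#' degrees-of-freedom-corrected moment estimator
#' `alpha = sum((y - mu)^2 - mu) / sum(mu^2) * n/(n - p)`. This removes
#' mouse-to-mouse variability from the dispersion, which the group-wise
#' estimator absorbs, and is what gives the paired design its precision
#' advantage.
#'
#' @param cm a [count_matrix()].
#' @param sf size factors from [size_factors()].
#' @param alpha_min dispersion floor.
#' @param method `"group"` (population-group moments, default) or
#'   `"design"` (residual moments around the paired-design fit).
#' @return data.frame: gene_id, dispersion, flagged (no usable group).
#' @export
estimate_dispersion <- function(cm, sf, alpha_min = 1e-8,
                                method = c("group", "design")) {
  method <- match.arg(method)
  norm <- sweep(cm$counts, 2, sf, "/")
  if (method == "design") {
    return(dispersion_by_design(cm, sf, norm, alpha_min))
  }
  pop <- cm$sample_meta$population
  per_group <- lapply(levels(pop), function(g) {
    x <- norm[, pop == g, drop = FALSE]
    if (ncol(x) < 2) return(NULL)
    m <- rowMeans(x)
    v <- apply(x, 1, stats::var)
    a <- ifelse(m > 0, pmax(0, (v - m) / m^2), NA_real_)
    a
  })
  per_group <- per_group[!vapply(per_group, is.null, logical(1))]
  amat <- do.call(cbind, per_group)
  disp <- rowMeans(amat, na.rm = TRUE)
  flagged <- !is.finite(disp)
  disp[flagged] <- alpha_min
  disp <- pmax(disp, alpha_min)
  data.frame(gene_id = rownames(cm$counts), dispersion = disp,
             flagged = flagged, row.names = NULL, stringsAsFactors = FALSE)
}

dispersion_by_design <- function(cm, sf, norm, alpha_min) {
  meta <- cm$sample_meta
  meta$population <- droplevels(meta$population)
  meta$mouse <- droplevels(meta$mouse)
  x <- if (nlevels(meta$mouse) > 1) {
    stats::model.matrix(~ mouse + population, meta)
  } else {
    stats::model.matrix(~ population, meta)
  }
  n <- nrow(x); p <- ncol(x)
  if (n <= p) stop("design leaves no residual degrees of freedom")
  # log-linear LS means on shifted normalized counts
  hat <- x %*% solve(crossprod(x), t(x))
  logy <- log(norm + 0.5)
  mu <- pmax(exp(logy %*% t(hat)) - 0.5, 1e-8)
  resid2 <- (norm - mu)^2
  # Var(K/s) = mu/s + alpha * mu^2 on the normalized scale
  num <- rowSums(resid2 - sweep(mu, 2, sf, "/"))
  den <- rowSums(mu^2)
  disp <- pmax(num / den * n / (n - p), 0)
  flagged <- rowSums(cm$counts) == 0
  disp[flagged | !is.finite(disp)] <- alpha_min
  disp <- pmax(disp, alpha_min)
  data.frame(gene_id = rownames(cm$counts), dispersion = disp,
             flagged = flagged, row.names = NULL, stringsAsFactors = FALSE)
}
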