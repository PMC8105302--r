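#' Paired negative-binomial Wald differential expression
#'
#' Fits, per gene, a log-link NB GLM with fixed gene-wise dispersion and
#' design `~ mouse + population` (intercept + mouse indicators + population
#' indicators), with `log(size factor)` as offset, by iteratively
#' reweighted least squares. The fit is batched across genes: all genes
#' share the design matrix, so each IRLS step reduces to per-gene weighted
#' normal equations assembled by matrix products. The Wald statistic is the
#' contrast estimate over its standard error, referred to a standard normal
#' (two-sided); every tested gene receives a p-value (no outlier cut-off,
#' no independent filtering).
#'
#' @param cm a [count_matrix()].
#' @param sf size factors from [size_factors()].
#' @param dispersions result of [estimate_dispersion()] (or a numeric
#'   vector, one dispersion per gene).
#' @param contrast character pair `c(numerator, denominator)` of population
#'   labels; default mature vs young tuft cells.
#' @param drop_zero_genes exclude genes with zero counts in all samples
#'   from testing (default TRUE).
#' @param paired include the mouse pairing factor in the design (default
#'   TRUE); `FALSE` fits `~ population` only, for design comparisons.
#' @param maxit,tol IRLS iteration cap and relative deviance tolerance.
#' @return data.frame: gene_id, base_mean, log2fc, se, wald_stat, p, padj,
#'   contrast, converged. Non-converged genes keep their estimate but have
#'   missing p/padj. Attribute `excluded_genes` lists dropped all-zero
#'   genes.
#' @export
fit_paired_nb_wald <- function(cm, sf, dispersions,
                               contrast = c("mature_tuft", "young_tuft"),
                               drop_zero_genes = TRUE, paired = TRUE,
                               maxit = 100L, tol = 1e-8) {
  meta <- cm$sample_meta
  meta$population <- droplevels(meta$population)
  meta$mouse <- droplevels(meta$mouse)
  pops <- levels(meta$population)
  if (!all(contrast %in% pops)) {
    stop("contrast populations must be among: ", paste(pops, collapse = ", "))
  }
  if (is.data.frame(dispersions)) {
    stopifnot(identical(dispersions$gene_id, rownames(cm$counts)))
    alpha <- dispersions$dispersion
  } else {
    alpha <- dispersions
  }
  stopifnot(length(alpha) == nrow(cm$counts), all(alpha > 0))

  k <- cm$counts
  excluded <- character()
  if (drop_zero_genes) {
    zero <- rowSums(k) == 0
    excluded <- rownames(k)[zero]
    k <- k[!zero, , drop = FALSE]
    alpha <- alpha[!zero]
  }
  g <- nrow(k)
  if (g == 0) stop("no genes left to test")

  x <- if (paired) {
    stats::model.matrix(~ mouse + population, data = meta)
  } else {
    stats::model.matrix(~ population, data = meta)
  }
  p <- ncol(x)
  if (qr(x)$rank < p) stop("rank-deficient design")
  # contrast vector on the dummy-coded population columns
  ref <- pops[1]
  pop_col <- function(lbl) {
    if (lbl == ref) return(numeric(p))
    cn <- paste0("population", lbl)
    v <- numeric(p); v[match(cn, colnames(x))] <- 1; v
  }
  v <- pop_col(contrast[1]) - pop_col(contrast[2])

  offset <- log(sf)
  norm <- sweep(k, 2, sf, "/")
  base_mean <- rowMeans(norm)

  fit <- nb_irls_batch(k, x, offset, alpha, maxit = maxit, tol = tol,
                       contrast_vec = v)
  est_nat <- fit$est
  se_nat <- fit$se
  log2fc <- est_nat / log(2)
  se <- se_nat / log(2)
  wald <- est_nat / se_nat
  pval <- 2 * stats::pnorm(-abs(wald))
  pval[!fit$converged] <- NA_real_
  padj <- rep(NA_real_, g)
  ok <- !is.na(pval)
  padj[ok] <- bh_adjust(pval[ok])
  res <- data.frame(gene_id = rownames(k), base_mean = base_mean,
                    log2fc = log2fc, se = se, wald_stat = wald,
                    p = pval, padj = padj,
                    contrast = paste(contrast, collapse = "_vs_"),
                    converged = fit$converged,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "excluded_genes") <- excluded
  res
}

# Batched IRLS for NB GLMs sharing one design matrix.
# k: G x N counts; x: N x p design; offset: length N; alpha: length G.
# Returns contrast estimate + SE (natural-log scale) and convergence flags.
nb_irls_batch <- function(k, x, offset, alpha, maxit = 100L, tol = 1e-8,
                          contrast_vec) {
  g <- nrow(k); n <- ncol(k); p <- ncol(x)
  # upper-triangle index pairs for assembling X'WX from a weight row
  ut <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  xx <- x[, ut[, 1], drop = FALSE] * x[, ut[, 2], drop = FALSE]  # N x p(p+1)/2

  # start from a log-linear least-squares fit on shifted normalized counts
  y0 <- log(sweep(k, 2, exp(offset), "/") + 0.5)
  beta <- y0 %*% x %*% solve(crossprod(x))

  dev_fun <- function(kk, mu, a) {
    t1 <- ifelse(kk > 0, kk * log(kk / mu), 0)
    t2 <- (kk + 1 / a) * log((1 + a * kk) / (1 + a * mu))
    2 * rowSums(t1 - t2)
  }

  active <- rep(TRUE, g)
  converged <- rep(FALSE, g)
  dev_old <- rep(Inf, g)
  est <- se <- rep(NA_real_, g)
  offmat <- matrix(offset, nrow = g, ncol = n, byrow = TRUE)

  for (it in seq_len(maxit)) {
    idx <- which(active)
    if (length(idx) == 0) break
    eta <- beta[idx, , drop = FALSE] %*% t(x) + offmat[idx, , drop = FALSE]
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    a <- alpha[idx]
    w <- mu / (1 + a * mu)                       # GLM weights, log link
    z <- eta - offmat[idx, , drop = FALSE] +
      (k[idx, , drop = FALSE] - mu) / mu          # working response
    xtwx <- w %*% xx                              # per-gene upper triangles
    xtwz <- (w * z) %*% x
    m <- matrix(0, p, p)
    for (r in seq_along(idx)) {
      m[upper.tri(m, diag = TRUE)] <- xtwx[r, ]
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      ch <- tryCatch(chol(m), error = function(e) NULL)
      if (is.null(ch)) next  # leave beta as-is; will fail convergence
      beta[idx[r], ] <- backsolve(ch, forwardsolve(t(ch), xtwz[r, ]))
    }
    dev <- dev_fun(k[idx, , drop = FALSE], mu, a)
    rel <- abs(dev - dev_old[idx]) / (abs(dev) + 0.1)
    done <- rel < tol
    converged[idx[done]] <- TRUE
    active[idx[done]] <- FALSE
    dev_old[idx] <- dev
  }

  # final covariance at the converged (or last) estimate
  eta <- beta %*% t(x) + offmat
  eta <- pmin(pmax(eta, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  xtwx <- w %*% xx
  m <- matrix(0, p, p)
  for (r in seq_len(g)) {
    m[upper.tri(m, diag = TRUE)] <- xtwx[r, ]
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    ch <- tryCatch(chol(m), error = function(e) NULL)
    if (is.null(ch)) { converged[r] <- FALSE; next }
    cov <- chol2inv(ch)
    est[r] <- sum(contrast_vec * beta[r, ])
    se[r] <- sqrt(drop(t(contrast_vec) %*% cov %*% contrast_vec))
  }
  list(beta = beta, est = est, se = se, converged = converged)
}
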