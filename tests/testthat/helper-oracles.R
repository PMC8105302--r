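# Independent oracles used against the package implementation.

# Direct NB log-likelihood maximization (Nelder-Mead from the data-driven
# start, polished by a coordinate-wise grid refinement). Independent of the
# IRLS path in the package.
nb_mle_oracle <- function(y, x, offset, alpha) {
  negll <- function(beta) {
    mu <- exp(drop(x %*% beta) + offset)
    -sum(stats::dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
  }
  init <- stats::coef(stats::lm(log(y / exp(offset) + 0.5) ~ x - 1))
  fit <- stats::optim(init, negll, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 50000))
  beta <- fit$par
  # coordinate-wise grid refinement around the optimum
  for (pass in 1:3) {
    step <- 10^-(2 + pass)
    for (j in seq_along(beta)) {
      grid <- beta[j] + seq(-25, 25) * step
      vals <- vapply(grid, function(b) {
        bb <- beta; bb[j] <- b; negll(bb)
      }, numeric(1))
      beta[j] <- grid[which.min(vals)]
    }
  }
  unname(beta)
}

# Exact two-sided Mann-Whitney p by full combinatorial enumeration of all
# C(N, n1) member assignments (tie-free scores only).
mww_enum_oracle <- function(scores, member_idx) {
  n <- length(scores)
  n1 <- length(member_idx)
  rk <- rank(scores)
  u_obs <- sum(rk[member_idx]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  u_all <- colSums(matrix(rk[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  p <- if (u_obs > mu) {
    2 * mean(u_all >= u_obs)
  } else {
    2 * mean(u_all <= u_obs)
  }
  min(p, 1)
}

# small paired fixture: 2 mice x 3 populations, 4 genes, printed counts
fixture_cm <- function() {
  counts <- rbind(
    gA = c(10L, 12L, 40L, 9L, 11L, 38L),
    gB = c(100L, 95L, 105L, 110L, 90L, 99L),
    gC = c(5L, 30L, 7L, 4L, 28L, 6L),
    gD = c(60L, 55L, 20L, 70L, 50L, 25L)
  )
  meta <- data.frame(
    sample = c("m1_bg", "m1_yt", "m1_mt", "m2_bg", "m2_yt", "m2_mt"),
    mouse = rep(c("m1", "m2"), each = 3),
    population = rep(c("background", "young_tuft", "mature_tuft"), 2),
    stringsAsFactors = FALSE
  )
  colnames(counts) <- meta$sample
  count_matrix(counts, meta)
}

# one-frame-per-row track builder for hand-constructed cases
make_track <- function(times, gfp, mcherry, cell = "c1") {
  data.frame(cell_id = cell, organoid_id = "o1", time_h = times,
             gfp = as.integer(gfp), mcherry = as.integer(mcherry),
             stringsAsFactors = FALSE)
}
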