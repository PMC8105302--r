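test_that("size factors: identity, hand-computed ratio, degenerate input", {
  meta2 <- data.frame(sample = c("s1", "s2"), mouse = c("m1", "m2"),
                      population = c("young_tuft", "young_tuft"))
  k <- matrix(c(10L, 10L, 40L, 40L, 7L, 7L), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), meta2$sample))
  expect_equal(unname(size_factors(count_matrix(k, meta2))), c(1, 1))

  k2 <- matrix(c(10L, 20L, 40L, 80L, 7L, 14L), nrow = 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), meta2$sample))
  # ratios (1, 2) per gene; after geometric-mean rescale: (1/sqrt2, sqrt2)
  expect_equal(unname(size_factors(count_matrix(k2, meta2))),
               c(1 / sqrt(2), sqrt(2)))

  k3 <- matrix(c(0L, 5L, 3L, 0L), nrow = 2,
               dimnames = list(c("a", "b"), meta2$sample))
  expect_error(size_factors(count_matrix(k3, meta2)),
               "strictly positive counts in all samples")
})

test_that("size factors scale with a uniform per-sample multiplier", {
  s <- simulate_counts(sim_config(n_genes = 300, n_de_genes = 0, seed = 3,
                                  library_size_mean = 1e5))
  cm <- s$cm
  sf1 <- size_factors(cm)
  k <- cm$counts
  k[, 1] <- k[, 1] * 4L
  cm2 <- count_matrix(k, cm$sample_meta)
  sf2 <- size_factors(cm2)
  # sample 1's factor quadruples relative to the others
  rel1 <- unname(sf1 / sf1[2])
  rel2 <- unname(sf2 / sf2[2])
  expect_equal(rel2[1] / rel1[1], 4, tolerance = 1e-6)
  expect_equal(rel2[-1], rel1[-1], tolerance = 1e-6)
  # and log2FC estimates are essentially unchanged; the NB likelihood is
  # not exactly scale-invariant, so count-limited genes move slightly more
  d1 <- fit_paired_nb_wald(cm, sf1, rep(0.05, 300))
  d2 <- fit_paired_nb_wald(cm2, sf2, rep(0.05, 300))
  dif <- abs(d2$log2fc - d1$log2fc)
  well_expressed <- d1$base_mean >= 10
  expect_lt(max(dif[well_expressed]), 0.02)
  expect_lt(max(dif), 0.1)
})

test_that("dispersion estimator: Poisson limit, NB recovery, zero genes", {
  s <- simulate_counts(sim_config(n_genes = 2000, n_de_genes = 0, de_lfc = 0,
                                  mouse_sd = 0, dispersion = 1e-8,
                                  library_size_mean = 4e5, seed = 6))
  sf <- size_factors(s$cm)
  d <- estimate_dispersion(s$cm, sf)
  # Poisson-simulated genes with mean count >= 100: near-zero dispersion
  big <- rowMeans(s$cm$counts) >= 100
  expect_lt(median(d$dispersion[big]), 0.01)

  s2 <- simulate_counts(sim_config(n_genes = 2000, n_de_genes = 0,
                                   de_lfc = 0, mouse_sd = 0,
                                   dispersion = 0.2,
                                   library_size_mean = 4e5, seed = 7))
  d2 <- estimate_dispersion(s2$cm, size_factors(s2$cm))
  expect_gt(median(d2$dispersion), 0.1)
  expect_lt(median(d2$dispersion), 0.3)

  cm <- fixture_cm()
  k <- cm$counts
  k[1, ] <- 0L
  cmz <- count_matrix(k, cm$sample_meta)
  dz <- estimate_dispersion(cmz, rep(1, 6))
  expect_true(dz$flagged[1])
  expect_equal(dz$dispersion[1], 1e-8)
})

test_that("identical contrast groups give null estimates", {
  cm <- fixture_cm()
  k <- cm$counts
  # make mature identical to young within each mouse
  k[, c(3, 6)] <- k[, c(2, 5)]
  cmn <- count_matrix(k, cm$sample_meta)
  de <- fit_paired_nb_wald(cmn, rep(1, 6), rep(0.1, 4))
  expect_equal(de$log2fc, rep(0, 4), tolerance = 1e-6)
  expect_true(all(de$p >= 0.99))
})

test_that("IRLS estimates match the direct NB likelihood oracle", {
  cm <- fixture_cm()
  sf <- size_factors(cm)
  alpha <- c(0.05, 0.1, 0.2, 0.02)
  de <- fit_paired_nb_wald(cm, sf, alpha)
  x <- model.matrix(~ mouse + population, cm$sample_meta)
  for (g in 1:4) {
    beta_hat <- nb_mle_oracle(cm$counts[g, ], x, log(sf), alpha[g])
    # contrast = mature - young coefficient difference
    est_oracle <- (beta_hat[match("populationmature_tuft", colnames(x))] -
                     beta_hat[match("populationyoung_tuft", colnames(x))])
    expect_equal(de$log2fc[g] * log(2), est_oracle, tolerance = 1e-4)
  }
})

test_that("IRLS agrees with a standard NB GLM fit at fixed dispersion", {
  skip_if_not_installed("MASS")
  cm <- fixture_cm()
  sf <- size_factors(cm)
  de <- fit_paired_nb_wald(cm, sf, rep(0.08, 4))
  for (g in 1:4) {
    fit <- suppressWarnings(stats::glm(
      cm$counts[g, ] ~ mouse + population + offset(log(sf)),
      data = cm$sample_meta, family = MASS::negative.binomial(1 / 0.08)))
    est <- unname(coef(fit)["populationmature_tuft"] -
                    coef(fit)["populationyoung_tuft"])
    expect_equal(de$log2fc[g] * log(2), est, tolerance = 1e-5)
  }
})

test_that("planted effects are recovered and the design pairing helps", {
  # deep libraries so overdispersion (mouse variance), not Poisson noise,
  # dominates for nearly every gene -- the regime where pairing pays off
  s <- simulate_counts(sim_config(n_genes = 400, n_de_genes = 60,
                                  de_lfc = 2, mouse_sd = 0.8,
                                  dispersion = 0.05,
                                  library_size_mean = 5e5, seed = 21))
  sf <- size_factors(s$cm)
  disp_p <- estimate_dispersion(s$cm, sf, method = "design")
  de_p <- fit_paired_nb_wald(s$cm, sf, disp_p)
  expect_equal(mean(de_p$log2fc[1:60]), 2, tolerance = 0.2)
  # unpaired analysis: group moments absorb the mouse-to-mouse variance
  disp_u <- estimate_dispersion(s$cm, sf)
  de_u <- fit_paired_nb_wald(s$cm, sf, disp_u, paired = FALSE)
  # with strong mouse effects the paired model is the more precise one
  expect_gt(mean(de_p$se < de_u$se), 0.9)
})

test_that("all-zero genes are excluded from testing but reported", {
  cm <- fixture_cm()
  k <- rbind(cm$counts, gZ = rep(0L, 6))
  cmz <- count_matrix(k, cm$sample_meta)
  de <- fit_paired_nb_wald(cmz, rep(1, 6), rep(0.1, 5))
  expect_equal(nrow(de), 4)
  expect_identical(attr(de, "excluded_genes"), "gZ")
})

test_that("rank-deficient designs are rejected", {
  cm <- fixture_cm()
  meta <- cm$sample_meta
  meta$mouse <- meta$sample  # one level per sample: saturated, deficient
  cmr <- count_matrix(cm$counts, meta)
  expect_error(fit_paired_nb_wald(cmr, rep(1, 6), rep(0.1, 4)),
               "rank-deficient")
})
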