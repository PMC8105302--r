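test_that("signed scores transform p and fold-change sign correctly", {
  de <- data.frame(gene_id = c("a", "b", "c"),
                   log2fc = c(5, -2, 1),
                   p = c(1, 0.01, 0.1), padj = c(1, 0.02, 0.2))
  sc <- signed_scores(de)
  expect_equal(sc$score, c(0, -2, 1))
  # antisymmetry: flipping every lfc negates every score
  de2 <- de; de2$log2fc <- -de2$log2fc
  expect_equal(signed_scores(de2)$score, -sc$score)
  # adjusted-p variant and the overflow floor
  expect_equal(signed_scores(de, use_adjusted = TRUE)$score[2],
               log10(0.02))  # -log10(padj) * sign(lfc) with lfc < 0
  de3 <- data.frame(gene_id = "x", log2fc = 1, p = 0)
  expect_equal(signed_scores(de3)$score, 300)
  expect_error(signed_scores(data.frame(gene_id = "x", log2fc = 1, p = 2)),
               "exceed 1")
})

test_that("sets outside the size bounds are excluded from testing and M", {
  scores <- data.frame(gene_id = sprintf("g%02d", 1:40),
                       score = seq(-2, 2, length.out = 40),
                       lfc = seq(-1, 1, length.out = 40),
                       p = rep(0.05, 40))
  sets <- list(tiny = sprintf("g%02d", 1:9),        # 9 members: dropped
               ok1 = sprintf("g%02d", 1:12),
               ok2 = sprintf("g%02d", 29:40))
  enr <- enrich_collection(scores, sets, min_size = 10, max_size = 500)
  expect_identical(sort(enr$set_name), c("ok1", "ok2"))
  expect_equal(attr(enr, "m_tests"), 2)
  expect_error(enrich_collection(scores, list(tiny = sprintf("g%02d", 1:5))),
               "size filter")
})

test_that("all-tied scores give p = 1 for every set", {
  scores <- data.frame(gene_id = sprintf("g%02d", 1:30),
                       score = rep(0, 30), lfc = rep(0, 30), p = rep(1, 30))
  sets <- list(s1 = sprintf("g%02d", 1:10), s2 = sprintf("g%02d", 11:25))
  enr <- suppressWarnings(enrich_collection(scores, sets))
  expect_equal(enr$p_enrich, c(1, 1))
})

test_that("exact-mode p matches full combinatorial enumeration", {
  # universe of 20 tie-free scores 1..20, set = top-ranked half
  scores <- data.frame(gene_id = sprintf("g%02d", 1:20), score = 1:20,
                       lfc = rep(1, 20), p = rep(0.01, 20))
  sets <- list(top = sprintf("g%02d", 11:20))
  enr <- enrich_collection(scores, sets)
  expect_true(enr$exact)
  p_oracle <- mww_enum_oracle(1:20, 11:20)
  expect_equal(enr$p_enrich, p_oracle, tolerance = 1e-9)

  # randomized tie-free cases, including a 25-gene universe
  set.seed(99)
  for (rep_i in 1:5) {
    n <- sample(15:25, 1)
    n1 <- sample(5:8, 1)
    sc <- sample(seq_len(200), n)
    idx <- sample(n, n1)
    scores <- data.frame(gene_id = sprintf("g%02d", 1:n), score = sc,
                         lfc = rnorm(n), p = runif(n))
    enr <- enrich_collection(scores,
                             list(s = sprintf("g%02d", idx)),
                             min_size = n1)
    expect_true(enr$exact)
    expect_equal(enr$p_enrich, mww_enum_oracle(sc, idx), tolerance = 1e-9)
    # normal approximation tracks the exact p; mid-distribution
    # discreteness can reach ~0.02 at these sizes
    enr_a <- enrich_collection(scores, list(s = sprintf("g%02d", idx)),
                               min_size = n1, exact_max_members = 0)
    expect_false(enr_a$exact)
    expect_lt(abs(enr_a$p_enrich - enr$p_enrich), 0.02)
  }
})

test_that("approximate p agrees with wilcox.test and limma's wilcoxGST", {
  set.seed(7)
  scores <- data.frame(gene_id = sprintf("g%03d", 1:300),
                       score = rnorm(300) + rep(c(1, 0), c(40, 260)),
                       lfc = rnorm(300), p = runif(300))
  idx <- c(1:40, 101:110)
  sets <- list(s = scores$gene_id[idx])
  enr <- enrich_collection(scores, sets)
  wt <- wilcox.test(scores$score[idx], scores$score[-idx],
                    exact = FALSE, correct = TRUE)
  expect_equal(enr$p_enrich, wt$p.value, tolerance = 1e-10)
  skip_if_not_installed("limma")
  p_limma <- limma::geneSetTest(seq_len(300) %in% idx, scores$score,
                                alternative = "either", ranks.only = TRUE)
  expect_equal(enr$p_enrich, p_limma, tolerance = 1e-10)
})

test_that("negating all scores preserves p and negates volcano x", {
  set.seed(12)
  n <- 200
  scores <- data.frame(gene_id = sprintf("g%03d", 1:n), score = rnorm(n),
                       lfc = rnorm(n), p = runif(n))
  scores$score <- -log10(scores$p) * sign(scores$lfc)
  sets <- list(a = scores$gene_id[1:30], b = scores$gene_id[50:120])
  e1 <- enrich_collection(scores, sets)
  neg <- scores
  neg$score <- -neg$score
  neg$lfc <- -neg$lfc
  e2 <- enrich_collection(neg, sets)
  expect_equal(e2$p_enrich, e1$p_enrich, tolerance = 1e-12)
  expect_equal(e2$x_volcano, -e1$x_volcano, tolerance = 1e-12)
})

test_that("volcano coordinates: hand example and degenerate weights", {
  scores <- data.frame(gene_id = c("a", "b"), score = c(1, 3),
                       lfc = c(1.0, 3.0), p = c(0.1, 0.001))
  v <- volcano_coordinates(scores, p_enrich = 0.01, members = c("a", "b"))
  expect_equal(v$x, 2.5)   # weights (1, 3): (1*1 + 3*3) / 4
  expect_equal(v$y, 2)
  # constant member lfc: weighted mean equals the constant
  sc2 <- data.frame(gene_id = c("a", "b"), score = c(1, 3),
                    lfc = c(0.7, 0.7), p = c(0.1, 0.001))
  expect_equal(volcano_coordinates(sc2, 0.5, c("a", "b"))$x, 0.7)
  # all member p = 1: zero weights, x missing with a warning
  sc3 <- data.frame(gene_id = c("a", "b"), score = c(0, 0),
                    lfc = c(1, 2), p = c(1, 1))
  expect_warning(v3 <- volcano_coordinates(sc3, 0.5, c("a", "b")), "zero")
  expect_true(is.na(v3$x))
})

test_that("null score permutation keeps the enrichment test calibrated", {
  set.seed(31)
  n <- 1000
  base_scores <- -log10(runif(n)) * sign(rnorm(n))
  uni <- sprintf("g%04d", 1:n)
  gs <- simulate_genesets(uni, n_sets = 100, size_range = c(10, 100),
                          seed = 17)
  hits <- 0; total <- 0
  for (round_i in 1:5) {
    scores <- data.frame(gene_id = uni, score = sample(base_scores),
                         lfc = rnorm(n), p = runif(n))
    enr <- enrich_collection(scores, gs$sets)
    hits <- hits + sum(enr$p_enrich < 0.05)
    total <- total + nrow(enr)
  }
  expect_lt(abs(hits / total - 0.05), 3 * sqrt(0.05 * 0.95 / total))
})
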