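expr_long <- function(m, ids, samples) {
  tibble::tibble(feature_id = rep(ids, each = length(samples)),
                 sample = rep(samples, length(ids)),
                 value = as.vector(t(m)))
}

smp9 <- sprintf("s%d", 1:9)

test_that("pair correlations hit the exact anchors and thresholds", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  ce <- expr_long(rbind(x, x), c("c_same", "c_rev"), smp9)
  ce$value[ce$feature_id == "c_rev"] <- rev(x)
  ge <- expr_long(rbind(x), "g1", smp9)
  pc <- pair_correlation(ce, ge,
                         tibble::tibble(circ_id = c("c_same", "c_rev"),
                                        gene_id = "g1"))
  expect_equal(pc$r, c(1, -1), tolerance = 1e-12)
  expect_equal(pc$class, c("sig_pos", "sig_neg"))
  expect_equal(pc$n, c(9, 9))
})

test_that("Pearson r matches the two-pass oracle and is symmetric", {
  withr::with_seed(12, {
    for (rep in 1:50) {
      x <- rnorm(9); y <- rnorm(9)
      ce <- expr_long(rbind(x), "c", smp9)
      ge <- expr_long(rbind(y), "g", smp9)
      pr <- tibble::tibble(circ_id = "c", gene_id = "g")
      r1 <- pair_correlation(ce, ge, pr)$r
      expect_equal(r1, pearson_oracle(x, y), tolerance = 1e-12)
      r2 <- pair_correlation(ge %>% dplyr::rename(circ_id = "feature_id"),
                             ce %>% dplyr::rename(gene_id = "feature_id"),
                             tibble::tibble(circ_id = "g", gene_id = "c"))$r
      expect_equal(r1, r2, tolerance = 1e-12)
    }
  })
})

test_that("degenerate correlation inputs are refused or flagged", {
  x <- 1:9
  ce <- expr_long(rbind(x), "c", smp9)
  ge <- expr_long(rbind(rep(1, 9)), "g", smp9)
  pc <- pair_correlation(ce, ge, tibble::tibble(circ_id = "c", gene_id = "g"))
  expect_true(pc$zero_variance)
  expect_true(is.na(pc$r))
  expect_equal(pc$class, "ns")
  two <- sprintf("s%d", 1:2)
  expect_error(pair_correlation(expr_long(rbind(1:2), "c", two),
                                expr_long(rbind(1:2), "g", two),
                                tibble::tibble(circ_id = "c", gene_id = "g")),
               "3")
  expect_error(pair_correlation(ce, ge,
                                tibble::tibble(circ_id = "nope",
                                               gene_id = "g")), "unknown")
})

test_that("correlated circRNA-parent pairs are recovered at the 9-sample design", {
  withr::with_seed(13, {
    hits <- 0; reps <- 500
    for (i in seq_len(reps)) {
      gene <- rnorm(9)
      z <- (gene - mean(gene)) / sd(gene)
      circ <- 0.9 * z + sqrt(1 - 0.81) * rnorm(9)
      r <- stats::cor.test(circ, gene)
      if (r$estimate >= 0.5 && r$p.value < 0.05) hits <- hits + 1
    }
    expect_gte(hits / reps, 0.8)
    # the same scenario through the package interface on a batch
    m_gene <- t(replicate(100, rnorm(9)))
    noise <- t(replicate(100, rnorm(9)))
    m_circ <- 0.9 * t(apply(m_gene, 1, scale)) + sqrt(1 - 0.81) * noise
    ids <- sprintf("f%03d", 1:100)
    pc <- pair_correlation(
      expr_long(m_circ, paste0("c_", ids), smp9),
      expr_long(m_gene, paste0("g_", ids), smp9),
      tibble::tibble(circ_id = paste0("c_", ids),
                     gene_id = paste0("g_", ids)))
    expect_gte(mean(pc$class == "sig_pos"), 0.8)
  })
})

test_that("module eigengenes summarize their module and flag members", {
  v <- c(5, 3, 1, 8, 2, 7, 4, 6, 9)
  m <- matrix(rep(v, 10), nrow = 10, byrow = TRUE) +
    withr::with_seed(14, matrix(rnorm(90, sd = 1e-6), nrow = 10))
  ids <- sprintf("g%02d", 1:10)
  ge <- expr_long(m, ids, smp9)
  ce <- expr_long(rbind(v, rev(v)), c("c_hit", "c_miss"), smp9)
  mc <- module_correlation(ce, ge, tibble::tibble(gene_id = ids,
                                                  module = "M1"))
  # eigengene is the shared profile up to scale: member |r| = 1
  e <- mc$eigengenes$value
  expect_equal(abs(pearson_oracle(e, v)), 1, tolerance = 1e-6)
  expect_gt(pearson_oracle(e, v), 0)  # sign follows the module mean
  hit <- mc$correlations[mc$correlations$circ_id == "c_hit", ]
  expect_equal(hit$r, 1, tolerance = 1e-6)
  expect_equal(hit$class, "sig_pos")
  # explained variance equals the leading eigenvalue fraction of the
  # module correlation matrix
  cmat <- stats::cor(t(m))
  ev <- eigen(cmat, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(mc$var_explained$prop_var, ev[1] / sum(ev),
               tolerance = 1e-6)
})

test_that("orthogonal planted modules attract only their own circRNAs", {
  withr::with_seed(15, {
    v1 <- scale(c(1, 5, 2, 8, 3, 9, 4, 7, 6))[, 1]
    v2_raw <- rnorm(9)
    v2 <- scale(stats::resid(stats::lm(v2_raw ~ v1)))[, 1]  # orthogonal
    m1 <- matrix(rep(v1, 8), nrow = 8, byrow = TRUE) +
      matrix(rnorm(72, sd = 0.05), nrow = 8)
    m2 <- matrix(rep(v2, 8), nrow = 8, byrow = TRUE) +
      matrix(rnorm(72, sd = 0.05), nrow = 8)
    ids <- sprintf("g%02d", 1:16)
    ge <- expr_long(rbind(m1, m2), ids, smp9)
    modules <- tibble::tibble(gene_id = ids,
                              module = rep(c("M1", "M2"), each = 8))
    ce <- expr_long(rbind(v1, v2), c("circ1", "circ2"), smp9)
    mc <- module_correlation(ce, ge, modules)
    cls <- mc$correlations
    expect_equal(cls$class[cls$circ_id == "circ1" & cls$module == "M1"],
                 "sig_pos")
    expect_equal(cls$class[cls$circ_id == "circ2" & cls$module == "M2"],
                 "sig_pos")
    expect_equal(cls$class[cls$circ_id == "circ1" & cls$module == "M2"],
                 "ns")
    expect_equal(cls$class[cls$circ_id == "circ2" & cls$module == "M1"],
                 "ns")
  })
})

test_that("tiny modules and constant modules are skipped with warnings", {
  ge <- expr_long(rbind(1:9, rep(2, 9), rep(3, 9)), c("g1", "g2", "g3"),
                  smp9)
  ce <- expr_long(rbind(1:9), "c", smp9)
  expect_warning(
    module_correlation(ce, ge, tibble::tibble(gene_id = "g1",
                                              module = "tiny")),
    "< 2")
  expect_warning(
    mc <- module_correlation(ce, ge,
                             tibble::tibble(gene_id = c("g2", "g3"),
                                            module = "flat")),
    "constant")
  expect_equal(nrow(mc$eigengenes), 0)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  bg <- sprintf("g%02d", 1:20)
  tm <- tibble::tibble(term = rep(c("T1", "T2"), c(8, 5)),
                       gene = c(bg[1:8], bg[10:14]))
  q <- c(bg[1:6], bg[10], bg[15])
  res <- hypergeom_enrichment(q, bg, tm)
  r1 <- res[res$term == "T1", ]
  expect_equal(r1$p, hyper_oracle(6, 8, 20, 8), tolerance = 1e-12)
  expect_equal(r1$fold_enrichment, (6 / 8) / (8 / 20))
  r2 <- res[res$term == "T2", ]
  expect_equal(r2$p, hyper_oracle(1, 5, 20, 8), tolerance = 1e-12)
  # full-overlap term has the smallest possible p and is significant
  res2 <- hypergeom_enrichment(bg[1:8], bg,
                               tibble::tibble(term = "T", gene = bg[1:8]))
  expect_equal(res2$p, hyper_oracle(8, 8, 20, 8), tolerance = 1e-12)
  expect_true(res2$significant)
  # random small backgrounds against the enumeration oracle
  withr::with_seed(16, {
    for (rep in 1:30) {
      N <- sample(10:25, 1)
      bgx <- sprintf("x%02d", seq_len(N))
      K <- sample(2:(N - 2), 1)
      nq <- sample(2:(N - 2), 1)
      tmx <- tibble::tibble(term = "T", gene = sample(bgx, K))
      qx <- sample(bgx, nq)
      k <- length(intersect(qx, tmx$gene))
      resx <- hypergeom_enrichment(qx, bgx, tmx)
      expect_equal(resx$p, hyper_oracle(k, K, N, nq), tolerance = 1e-12)
    }
  })
})

test_that("enrichment gates and errors behave", {
  bg <- sprintf("g%02d", 1:30)
  tm <- tibble::tibble(term = "T", gene = bg[1:10])
  # zero overlap: p = 1, not significant
  r0 <- hypergeom_enrichment(bg[25:30], bg, tm)
  expect_equal(r0$p, 1)
  expect_false(r0$significant)
  # overlap 2 with min_count 3 can never be significant
  r2 <- hypergeom_enrichment(bg[c(1, 2, 25, 26)], bg, tm)
  expect_equal(r2$genes_in_query, 2)
  expect_false(r2$significant)
  expect_error(hypergeom_enrichment("g", character(0), tm), "background")
  expect_error(hypergeom_enrichment("zzz", bg, tm), "not in background")
})

test_that("random queries are not spuriously enriched", {
  withr::with_seed(18, {
    bg <- sprintf("g%03d", 1:200)
    tm <- tibble::tibble(term = rep(sprintf("T%d", 1:10), each = 20),
                         gene = sample(bg, 200, replace = TRUE))
    n_sig <- 0; n_terms <- 0
    for (rep in 1:200) {
      q <- sample(bg, 30)
      res <- hypergeom_enrichment(q, bg, tm)
      n_sig <- n_sig + sum(res$p < 0.05)
      n_terms <- n_terms + nrow(res)
    }
    expect_lte(n_sig / n_terms, 0.07)
  })
})
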