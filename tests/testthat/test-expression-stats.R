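makeExpr <- function(mat, unit = "counts", geneInfo = NULL, cohort = NULL) {
  GeneExpression(mat, unit = unit, geneInfo = geneInfo, cohort = cohort)
}

test_that("subset CPM is exact and scale-invariant", {
  mat <- matrix(c(2, 999998, 10, 1e6 - 10), 2, 2,
                dimnames = list(c("gA", "chr10ref"), c("s1", "s2")))
  em <- makeExpr(mat)
  cpm <- cpmSubsetNormalize(em)   # reference = all genes, totals = 1e6
  expect_equal(assay(cpm)["gA", ], c(s1 = 2, s2 = 10))
  expect_equal(exprUnit(cpm), "CPM")

  # doubling one sample's counts leaves its CPM unchanged
  mat2 <- mat; mat2[, 1] <- mat2[, 1] * 2
  cpm2 <- cpmSubsetNormalize(makeExpr(mat2))
  expect_equal(assay(cpm2), assay(cpm))

  # chromosome-subset denominator uses only the reference genes
  sub <- cpmSubsetNormalize(em, reference = "chr10ref")
  expect_equal(assay(sub)["gA", "s1"], 2 / 999998 * 1e6)

  zero <- makeExpr(matrix(c(1, 0), 1, 2,
                          dimnames = list("g", c("ok", "empty"))))
  expect_error(cpmSubsetNormalize(zero), "empty")
})

test_that("RPKM follows count / (kb x million reads)", {
  mat <- matrix(c(10, 10, 0), 3, 1,
                dimnames = list(c("g1k", "g2k", "gz"), "s1"))
  em <- makeExpr(mat, geneInfo = data.frame(length = c(1000, 2000, 500)))
  r <- rpkmNormalize(em, totalReads = 1e6)
  expect_equal(unname(assay(r)[, 1]), c(10, 5, 0))
  noLen <- makeExpr(mat)
  expect_error(rpkmNormalize(noLen, totalReads = 1e6), "length")
})

test_that("quantile split labels strictly beyond the quartiles", {
  g <- quantileSplit(1:100)
  expect_equal(sum(g == "low"), 25)
  expect_equal(sum(g == "high"), 25)
  # interpolated quantiles of 1..8 are 2.75 / 6.25
  g8 <- quantileSplit(1:8)
  expect_identical(as.character(g8),
                   c("low", "low", "mid", "mid", "mid", "mid",
                     "high", "high"))
  expect_warning(gc <- quantileSplit(rep(3, 10)), "degenerate")
  expect_true(all(gc == "mid"))
  expect_error(quantileSplit(1:5), ">= 8")
})

test_that("two-group DE recovers exact fold changes and a clean null", {
  # noise-free planted 4-fold gene: log2fc exactly 2 at offset 0
  mat <- rbind(flat = rep(8, 8), de = rep(c(40, 10), each = 4))
  colnames(mat) <- sprintf("s%d", 1:8)
  em <- makeExpr(mat)
  res <- twoGroupDE(em, sprintf("s%d", 1:4), sprintf("s%d", 5:8),
                    offset = 0)
  expect_equal(res$log2fc[res$gene_id == "de"], 2)
  expect_equal(res$p[res$gene_id == "de"], 0)    # zero within-group variance
  expect_equal(res$log2fc[res$gene_id == "flat"], 0)
  expect_equal(res$p[res$gene_id == "flat"], 1)  # degenerate null, not NaN
  expect_true(all(res$p_adj >= res$p))
  expect_error(twoGroupDE(em, "s1", sprintf("s%d", 5:8)), ">= 2 samples")
})

test_that("BH adjustment matches the brute-force step-up procedure", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(21)
  for (i in 1:10) {
    p <- runif(sample(5:400, 1))
    expect_equal(bhAdjust(p), bhOracle(p), tolerance = 1e-12)
  }
})

test_that("the DEG filter applies all clauses and is monotone in minRpkm", {
  deg <- data.frame(
    gene_id = sprintf("g%d", 1:6),
    log2fc = c(2, 2, 2, 0.5, -3, 1.5),
    p = 0.001,
    p_adj = c(0.01, 0.01, 0.2, 0.01, 0.01, 0.01))
  rmat <- matrix(c(5, 5, 5, 5, 5, 0.2,
                   5, 5, 5, 5, 5, 0.2), 6, 2,
                 dimnames = list(deg$gene_id, c("a1", "b1")))
  rmat <- cbind(rmat, rmat)
  colnames(rmat) <- c("a1", "b1", "a2", "b2")
  rpkm <- makeExpr(rmat, unit = "RPKM",
                   geneInfo = data.frame(
                     biotype = c("coding", "noncoding", "coding",
                                 "coding", "coding", "coding")))
  grpA <- c("a1", "a2"); grpB <- c("b1", "b2")
  # g1 passes all clauses; g5 passes (|lfc|>1, adj ok, abundant);
  # g2 noncoding, g3 fails p_adj, g4 fails lfc, g6 fails abundance
  expect_setequal(degFilter(deg, rpkm, grpA, grpB, codingOnly = TRUE),
                  c("g1", "g5"))
  loose <- degFilter(deg, rpkm, grpA, grpB, minRpkm = 0,
                     codingOnly = TRUE)
  expect_true(all(degFilter(deg, rpkm, grpA, grpB,
                            codingOnly = TRUE) %in% loose))
  expect_equal(degFilter(deg[0, ], rpkm, grpA, grpB), character(0))
})

test_that("correlation screen matches the closed-form Pearson statistic", {
  set.seed(31)
  n <- 40
  mat <- matrix(rlnorm(20 * n), 20, n,
                dimnames = list(sprintf("g%02d", 1:20),
                                sprintf("s%02d", 1:n)))
  mat[2, ] <- 3 * mat[1, ] + 5          # exact affine transform of target
  mat[3, ] <- 7                          # zero variance
  em <- makeExpr(mat, unit = "TPM")
  res <- correlationScreen(em, "g01")
  expect_false("g01" %in% res$gene_id)
  expect_equal(res$r[res$gene_id == "g02"], 1)
  expect_lt(res$p[res$gene_id == "g02"], 1e-12)
  expect_true(res$zero_variance[res$gene_id == "g03"])
  expect_false(res$significant[res$gene_id == "g03"])
  # closed form vs cor() / t distribution
  for (g in c("g04", "g10", "g17")) {
    rr <- cor(mat["g01", ], mat[g, ])
    expect_equal(res$r[res$gene_id == g], rr, tolerance = 1e-12)
    tt <- rr * sqrt((n - 2) / (1 - rr^2))
    expect_equal(res$p[res$gene_id == g], 2 * pt(-abs(tt), n - 2),
                 tolerance = 1e-12)
  }
  expect_identical(res$direction[res$gene_id == "g02"], "positive")
})

test_that("DEG-set intersection is case-normalized and exact", {
  expect_equal(intersectDegSets(c("a", "b"), c("c", "d"))$n_overlap, 0)
  sub <- intersectDegSets(c("A", "B"), c("a", "b", "c"))
  expect_equal(sub$n_overlap, 2)
  expect_equal(sub$n_b_only, 1)
  expect_equal(intersectDegSets("WASF3", "wasf3")$overlap, "WASF3")
})
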