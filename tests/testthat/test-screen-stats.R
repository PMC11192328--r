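makeCounts <- function(lib, t0, endpoint) {
  mat <- cbind(T0_r1 = as.integer(t0), endpoint_r1 = as.integer(endpoint))
  rownames(mat) <- sgrnaIds(lib)
  ScreenCounts(mat, lib, condition = c("T0", "endpoint"),
               replicate = c(1L, 1L))
}

test_that("phenotypes are NTC-centred log2 rpm ratios with the stated sign", {
  lib <- toyLibrary(1L, 2L, 4L)   # gene01_sg1/2 + 4 NTCs
  # NTC rpm ratio 1, targeting rpm ratio 4 -> phenotype log2(4) = 2
  t0 <- c(1e4, 1e4, rep(1e4, 4))
  ep <- c(4e4, 4e4, rep(1e4, 4))
  phen <- computePhenotypes(makeCounts(lib, t0, ep))
  expect_equal(phen$phenotype[!phen$is_ntc], c(2, 2), tolerance = 1e-3)
  expect_equal(median(phen$phenotype[phen$is_ntc]), 0, tolerance = 1e-9)

  # endpoint identical to T0: all phenotypes 0
  phen0 <- computePhenotypes(makeCounts(lib, t0, t0))
  expect_equal(phen0$phenotype, rep(0, 6))

  # depth invariance: scaling a sample's counts changes nothing
  phen2 <- computePhenotypes(makeCounts(lib, t0, ep * 3))
  expect_equal(phen2$phenotype, phen$phenotype)

  # missing endpoint / zero-sum samples are refused
  expect_error(computePhenotypes(makeCounts(lib, t0, ep), replicate = 2),
               "lacks a T0")
  zc <- suppressWarnings(makeCounts(lib, t0, rep(0, 6)))
  expect_error(computePhenotypes(zc), "zero-sum")
})

test_that("replicate averaging is the arithmetic mean over matched sgRNAs", {
  a <- phenTable(c(1, 0.8), c("g1", "g1"), c(FALSE, FALSE))
  a$phenotype <- a$phenotype_mean
  b <- a; b$phenotype <- c(-1, 1.2)
  avg <- averageReplicates(list(a, b))
  expect_equal(avg$phenotype_mean, c(0, 1))
  expect_equal(avg$phenotype_rep2, c(-1, 1.2))
  bad <- b; bad$sgrna_id <- c("zz1", "zz2")
  expect_error(averageReplicates(list(a, bad)), "mismatched sgRNA set")
  expect_equal(averageReplicates(list(a, a))$phenotype_mean, a$phenotype)
})

test_that("gene scoring follows the top-3 x -log10(p) definition", {
  # gene with phenotypes {2,2,2,0x7} against 12 null NTCs: top-3 mean = 2
  phen <- phenTable(c(rep(2, 3), rep(0, 7), rep(0, 12)),
                    c(rep("g1", 10), rep("NTC", 12)),
                    c(rep(FALSE, 10), rep(TRUE, 12)))
  sc <- geneScores(phen)
  expect_equal(sc$avg_top3_phenotype, 2)
  expect_equal(sc$n_sgrnas, 10L)
  expect_gt(sc$screen_score, 0)

  # gene indistinguishable from the NTCs: p = 1, score = 0
  null <- phenTable(c(rep(0, 5), rep(0, 12)),
                    c(rep("g1", 5), rep("NTC", 12)),
                    c(rep(FALSE, 5), rep(TRUE, 12)))
  sc0 <- geneScores(null)
  expect_equal(sc0$mw_p, 1)
  expect_equal(sc0$screen_score, 0)

  # |avg_top3| never exceeds the gene's largest |phenotype|
  set.seed(3)
  rnd <- phenTable(c(rnorm(10), rnorm(15)),
                   c(rep("g1", 10), rep("NTC", 15)),
                   c(rep(FALSE, 10), rep(TRUE, 15)))
  scr <- geneScores(rnd)
  expect_lte(abs(scr$avg_top3_phenotype),
             max(abs(rnd$phenotype_mean[!rnd$is_ntc])))
  expect_equal(sign(scr$screen_score), sign(scr$avg_top3_phenotype))

  # genes with < 2 sgRNAs are excluded with a warning
  lone <- phenTable(c(1, 0, 0, rep(0, 12)),
                    c("solo", "g2", "g2", rep("NTC", 12)),
                    c(rep(FALSE, 3), rep(TRUE, 12)))
  expect_warning(scl <- geneScores(lone), "solo")
  expect_false("solo" %in% scl$gene_id)
  expect_error(geneScores(phen[1:12, ]), ">= 10 NTC")
})

test_that("a strongly planted gene attains the maximum screen score", {
  sim <- simulateScreen(screenSimConfig(nGenes = 100L, nNTC = 247L,
                                        nHits = 1L,
                                        effectRange = c(1, 1),
                                        positiveOnly = TRUE,
                                        efficacyShape = NULL),
                        seed = 5)
  sc <- geneScores(screenPhenotypes(sim$counts))
  planted <- sim$truth$gene_id[sim$truth$is_hit]
  expect_equal(sc$gene_id[which.max(sc$screen_score)], planted)
})

test_that("pseudo-genes reproduce by seed and are null on null data", {
  phen <- phenTable(c(rep(0, 20), rep(0, 30)),
                    c(rep(c("g1", "g2"), each = 10), rep("NTC", 30)),
                    c(rep(FALSE, 20), rep(TRUE, 30)))
  p1 <- pseudoGeneScores(phen, nPseudo = 25, seed = 9)
  p2 <- pseudoGeneScores(phen, nPseudo = 25, seed = 9)
  expect_identical(p1, p2)
  expect_true(all(p1$screen_score == 0))   # all-zero phenotypes
  expect_true(all(p1$is_pseudo))
  expect_equal(p1$n_sgrnas, rep(10L, 25))  # modal sgRNAs/gene default
  expect_error(pseudoGeneScores(phen, nPseudo = 0), "positive")
})

test_that("hit calling applies both thresholds and the pseudo-gene FDR", {
  sc <- data.frame(
    gene_id = sprintf("g%d", 1:6),
    n_sgrnas = 10L,
    avg_top3_phenotype = c(0.8, 0.8, 0.8, 0.9, 0.9, 0.1),
    mw_p = c(0.001, 0.001, 0.001, 0.2, 0.2, 0.001),
    screen_score = 1, is_pseudo = FALSE)
  ps <- data.frame(gene_id = "p1", n_sgrnas = 10L,
                   avg_top3_phenotype = 0, mw_p = 1,
                   screen_score = 0, is_pseudo = TRUE)
  called <- callHits(sc, ps, pThreshold = 0.05, effectThreshold = 0.415)
  expect_equal(sum(called$scores$hit), 3L)
  expect_equal(called$summary$n_hits_positive, 3L)
  expect_equal(called$summary$empirical_fdr, 0)

  # nothing passes: FDR is unavailable, not zero
  none <- callHits(sc, ps, pThreshold = 0.05, effectThreshold = 5)
  expect_equal(sum(none$scores$hit), 0L)
  expect_true(is.na(none$summary$empirical_fdr))
  expect_error(callHits(sc, ps, pThreshold = 2), "pThreshold")
})

test_that("volcano table mirrors the scored genes row for row", {
  phen <- phenTable(c(rep(1.5, 3), rep(0, 7), rnorm(15, 0, 0.01)),
                    c(rep("g1", 10), rep("NTC", 15)),
                    c(rep(FALSE, 10), rep(TRUE, 15)))
  sc <- geneScores(phen)
  ps <- pseudoGeneScores(phen, nPseudo = 5, seed = 1)
  v <- volcanoTable(sc, ps)
  expect_equal(nrow(v), nrow(sc) + nrow(ps))
  expect_true(all(v$neg_log10_p >= 0))
  top <- v[which.max(v$screen_score), ]
  expect_equal(top$gene_id, sc$gene_id[which.max(sc$screen_score)])
})
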