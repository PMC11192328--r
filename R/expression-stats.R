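#' CPM normalization against a reference gene subset
#'
#' Computes counts-per-million where the per-sample denominator is the
#' total count over a reference subset of genes rather than the whole
#' matrix — e.g. all chromosome-10 genes when quantifying a chromosome-10
#' locus, which shields the unit from library-composition differences on
#' other chromosomes:
#' \code{cpm(g,s) = count(g,s) / sum(count(reference, s)) * 1e6}.
#'
#' @param em a \linkS4class{GeneExpression} in counts.
#' @param reference character vector of reference gene ids (default: all
#'   genes, i.e. ordinary CPM).
#' @return A \linkS4class{GeneExpression} with unit \code{"CPM"}.
#' @export
cpmSubsetNormalize <- function(em, reference = rownames(em)) {
  stopifnot(is(em, "GeneExpression"))
  if (exprUnit(em) != "counts") stop("input must be in counts")
  reference <- intersect(reference, rownames(em))
  if (!length(reference)) stop("reference subset is empty")
  mat <- assay(em)
  tot <- colSums(mat[reference, , drop = FALSE])
  if (any(tot == 0))
    stop("zero reference total in sample(s): ",
         paste(colnames(mat)[tot == 0], collapse = ", "))
  out <- em
  assays(out)$abundance <- sweep(mat, 2L, tot, "/") * 1e6
  metadata(out)$unit <- "CPM"
  metadata(out)$cpm_reference_n <- length(reference)
  out
}

#' RPKM normalization
#'
#' \code{rpkm(g,s) = count(g,s) / (length_kb(g) * total_millions(s))},
#' with gene lengths (bp) taken from \code{rowData(em)$length}.
#'
#' @param em a \linkS4class{GeneExpression} in counts with per-gene
#'   \code{length}.
#' @param totalReads per-sample totals of assigned reads; defaults to the
#'   matrix column sums.
#' @return A \linkS4class{GeneExpression} with unit \code{"RPKM"}.
#' @export
rpkmNormalize <- function(em, totalReads = colSums(assay(em))) {
  stopifnot(is(em, "GeneExpression"))
  if (exprUnit(em) != "counts") stop("input must be in counts")
  len <- rowData(em)$length
  if (is.null(len) || anyNA(len))
    stop("rowData(em)$length (bp) is required for RPKM")
  if (any(totalReads <= 0)) stop("totalReads must be positive")
  out <- em
  assays(out)$abundance <-
    sweep(assay(em) / (len / 1e3), 2L, totalReads / 1e6, "/")
  metadata(out)$unit <- "RPKM"
  out
}

#' Quantile cohort stratification
#'
#' Splits samples into \code{"low"} / \code{"mid"} / \code{"high"} groups
#' by the empirical quantiles of a target gene's expression: high is
#' strictly above the upper quantile, low strictly below the lower one,
#' and boundary ties go to mid, so the split is deterministic. Quantiles
#' use linear interpolation (R type 7).
#'
#' @param values numeric vector (one value per sample), length >= 8.
#' @param lowerQ,upperQ quantile probabilities (defaults 0.25 and 0.75,
#'   i.e. the lower/upper 25 percent).
#' @return A factor with levels \code{low}, \code{mid}, \code{high}.
#' @export
quantileSplit <- function(values, lowerQ = 0.25, upperQ = 0.75) {
  if (length(values) < 8L) stop("need >= 8 values")
  q <- stats::quantile(values, c(lowerQ, upperQ), type = 7, names = FALSE)
  if (q[1] == q[2]) {
    warning("degenerate (near-constant) vector: all samples labelled mid")
    return(factor(rep("mid", length(values)),
                  levels = c("low", "mid", "high")))
  }
  lab <- rep("mid", length(values))
  lab[values < q[1]] <- "low"
  lab[values > q[2]] <- "high"
  factor(lab, levels = c("low", "mid", "high"))
}

#' Two-group differential expression (Welch t on log2 abundances)
#'
#' Per gene: \code{log2fc = mean(log2(x + offset)) in A - same in B}, with
#' a two-sided Welch (unequal-variance) t test on the log2 values and
#' Benjamini-Hochberg adjustment over all tested genes. Genes with zero
#' variance in both groups get p = 1 when the means are equal and p = 0
#' otherwise (a noise-free planted fold change is "infinitely"
#' significant). This is a deliberately simple, self-contained DE stage;
#' it is not a shrinkage-based count model.
#'
#' @param em a \linkS4class{GeneExpression} (any unit).
#' @param groupA,groupB character vectors of sample ids, each of length
#'   >= 2.
#' @param offset positive value added before the log2 transform
#'   (default 0.5).
#' @return A data frame with one row per gene: \code{gene_id},
#'   \code{log2fc}, \code{mean_a}, \code{mean_b} (group means on the raw
#'   scale), \code{p}, \code{p_adj}.
#' @export
twoGroupDE <- function(em, groupA, groupB, offset = 0.5) {
  stopifnot(is(em, "GeneExpression"))
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs >= 2 samples")
  miss <- setdiff(c(groupA, groupB), colnames(em))
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  la <- log2(assay(em)[, groupA, drop = FALSE] + offset)
  lb <- log2(assay(em)[, groupB, drop = FALSE] + offset)
  na <- ncol(la); nb <- ncol(lb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1L, stats::var); vb <- apply(lb, 1L, stats::var)
  sa <- va / na; sb <- vb / nb
  tstat <- (ma - mb) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- (va == 0 & vb == 0)
  p[degenerate] <- ifelse(ma[degenerate] == mb[degenerate], 1, 0)
  data.frame(gene_id = rownames(em), log2fc = unname(ma - mb),
             mean_a = unname(rowMeans(assay(em)[, groupA, drop = FALSE])),
             mean_b = unname(rowMeans(assay(em)[, groupB, drop = FALSE])),
             p = unname(p), p_adj = bhAdjust(unname(p)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (monotone in rank, capped at 1), via
#' \code{stats::p.adjust(method = "BH")} after range validation.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return The adjusted vector.
#' @export
bhAdjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differentially-expressed-gene filter
#'
#' A gene passes when \code{|log2fc| > lfcThreshold}, \code{p_adj <
#' alpha}, its group-mean RPKM is at least \code{minRpkm} in either
#' group, and (optionally) its biotype is coding.
#'
#' @param deg a DEG table from [twoGroupDE()].
#' @param rpkm a \linkS4class{GeneExpression} in RPKM over the same genes.
#' @param groupA,groupB sample ids of the two groups in \code{rpkm}.
#' @param lfcThreshold,alpha,minRpkm filter constants (defaults 1, 0.05, 1).
#' @param codingOnly if \code{TRUE}, require
#'   \code{rowData(rpkm)$biotype == "coding"}.
#' @return Character vector of passing gene ids.
#' @export
degFilter <- function(deg, rpkm, groupA, groupB, lfcThreshold = 1,
                      alpha = 0.05, minRpkm = 1, codingOnly = FALSE) {
  stopifnot(is(rpkm, "GeneExpression"))
  idx <- match(deg$gene_id, rownames(rpkm))
  if (anyNA(idx))
    stop("DEG gene(s) absent from the RPKM matrix: ",
         paste(utils::head(deg$gene_id[is.na(idx)], 5L), collapse = ", "))
  ra <- rowMeans(assay(rpkm)[idx, groupA, drop = FALSE])
  rb <- rowMeans(assay(rpkm)[idx, groupB, drop = FALSE])
  pass <- abs(deg$log2fc) > lfcThreshold & deg$p_adj < alpha &
    (ra >= minRpkm | rb >= minRpkm)
  if (codingOnly) {
    bio <- rowData(rpkm)$biotype
    if (is.null(bio)) stop("codingOnly requires rowData(rpkm)$biotype")
    pass <- pass & bio[idx] == "coding"
  }
  deg$gene_id[pass]
}

#' Genome-wide Pearson correlation screen against a target gene
#'
#' Correlates every gene with the target gene across samples; the
#' two-sided p-value comes from the t distribution with n - 2 degrees of
#' freedom. The target itself is excluded from the output. Zero-variance
#' genes get an undefined r and are reported non-significant with a flag.
#'
#' @param em a \linkS4class{GeneExpression} (>= 4 samples).
#' @param target gene id of the target (must be a row of \code{em}).
#' @param alpha significance level for the \code{significant} flag
#'   (default 0.05).
#' @return A data frame per non-target gene: \code{gene_id}, \code{r},
#'   \code{p}, \code{significant}, \code{direction}
#'   (\code{"positive"} / \code{"negative"} / \code{NA}),
#'   \code{zero_variance}.
#' @export
correlationScreen <- function(em, target, alpha = 0.05) {
  stopifnot(is(em, "GeneExpression"))
  if (!target %in% rownames(em)) stop("target gene not found: ", target)
  n <- ncol(em)
  if (n < 4L) stop("need >= 4 samples")
  mat <- assay(em)
  tv <- mat[target, ]
  if (stats::sd(tv) == 0) stop("target gene has zero variance")
  others <- setdiff(rownames(mat), target)
  x <- mat[others, , drop = FALSE]
  xc <- x - rowMeans(x)
  tc <- tv - mean(tv)
  ss <- rowSums(xc^2)
  r <- as.numeric(xc %*% tc) / sqrt(ss * sum(tc^2))
  zeroVar <- ss == 0
  r[zeroVar] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[zeroVar] <- NA_real_
  sig <- !is.na(p) & p < alpha
  data.frame(gene_id = others, r = r, p = p, significant = sig,
             direction = ifelse(is.na(r), NA_character_,
                                ifelse(r > 0, "positive", "negative")),
             zero_variance = zeroVar,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Intersect two differentially-expressed gene sets
#'
#' Gene symbols are upper-cased before the set operation (cohort tables
#' mix capitalizations of the same symbol), and the exclusive counts are
#' returned ready for a two-set Venn diagram.
#'
#' @param setA,setB character vectors of gene symbols.
#' @return A list: \code{overlap} (sorted common symbols),
#'   \code{n_overlap}, \code{n_a_only}, \code{n_b_only}, \code{n_a},
#'   \code{n_b}.
#' @export
intersectDegSets <- function(setA, setB) {
  a <- unique(toupper(setA)); b <- unique(toupper(setB))
  ov <- sort(intersect(a, b))
  list(overlap = ov, n_overlap = length(ov),
       n_a_only = length(setdiff(a, b)), n_b_only = length(setdiff(b, a)),
       n_a = length(a), n_b = length(b))
}
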