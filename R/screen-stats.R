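#' sgRNA invasion phenotypes for one screen replicate
#'
#' Converts T0 and endpoint counts of one replicate to per-sgRNA log2
#' invasion phenotypes. Counts are scaled to reads per million (rpm), a
#' pseudocount is added after scaling, and the raw value is
#' \code{log2((endpoint_rpm + pc) / (T0_rpm + pc))}; the phenotype is the
#' raw value minus the median raw value over the non-targeting controls,
#' so the NTC median phenotype is exactly zero in every replicate and the
#' statistic is invariant to sequencing depth.
#'
#' Sign convention: the screen harvests the non-invading population, so a
#' positive phenotype means the sgRNA was enriched among non-invaders,
#' i.e. knockdown of its target decreased invasion.
#'
#' @param counts a \linkS4class{ScreenCounts}.
#' @param replicate which replicate to use (must have both a T0 and an
#'   endpoint sample).
#' @param pseudocount positive pseudocount added after rpm scaling
#'   (default 1).
#' @return A data frame with columns \code{sgrna_id}, \code{gene_id},
#'   \code{is_ntc}, \code{phenotype}.
#' @export
computePhenotypes <- function(counts, replicate = 1L, pseudocount = 1) {
  stopifnot(is(counts, "ScreenCounts"))
  if (pseudocount <= 0) stop("pseudocount must be positive")
  cd <- colData(counts)
  pick <- function(cond) {
    j <- which(cd$condition == cond & cd$replicate == replicate)
    if (!length(j))
      stop("replicate ", replicate, " lacks a ", cond, " sample")
    j[1L]
  }
  j0 <- pick("T0"); j1 <- pick("endpoint")
  if (!cd$usable[j0] || !cd$usable[j1])
    stop("zero-sum sample in replicate ", replicate)
  mat <- assay(counts, "counts")
  rpm <- function(v) v / sum(v) * 1e6
  raw <- log2((rpm(mat[, j1]) + pseudocount) /
              (rpm(mat[, j0]) + pseudocount))
  ntc <- isNTC(counts)
  phen <- raw - stats::median(raw[ntc])
  data.frame(sgrna_id = sgrnaIds(counts),
             gene_id = rowData(counts)$gene_id,
             is_ntc = ntc, phenotype = unname(phen),
             stringsAsFactors = FALSE)
}

#' Average sgRNA phenotypes across screen replicates
#'
#' @param tables a list of two or more phenotype tables from
#'   [computePhenotypes()], one per replicate, over identical sgRNA sets.
#' @return A data frame with the per-replicate phenotypes
#'   (\code{phenotype_rep<k>}) and their arithmetic mean
#'   \code{phenotype_mean}.
#' @export
averageReplicates <- function(tables) {
  if (!is.list(tables) || length(tables) < 2L)
    stop("need a list of >= 2 replicate phenotype tables")
  ref <- tables[[1L]]
  out <- ref[, c("sgrna_id", "gene_id", "is_ntc")]
  for (k in seq_along(tables)) {
    tab <- tables[[k]]
    if (!setequal(tab$sgrna_id, ref$sgrna_id))
      stop("replicate ", k, " has a mismatched sgRNA set")
    tab <- tab[match(ref$sgrna_id, tab$sgrna_id), ]
    out[[paste0("phenotype_rep", k)]] <- tab$phenotype
  }
  out$phenotype_mean <-
    rowMeans(as.matrix(out[, grep("^phenotype_rep", names(out))]))
  out
}

#' All-replicate phenotypes in one call
#'
#' Convenience wrapper: computes [computePhenotypes()] for every replicate
#' present in the object and averages them with [averageReplicates()]
#' (single-replicate screens are returned with
#' \code{phenotype_mean = phenotype_rep1}).
#'
#' @inheritParams computePhenotypes
#' @return The averaged phenotype table.
#' @export
screenPhenotypes <- function(counts, pseudocount = 1) {
  reps <- sort(unique(colData(counts)$replicate))
  tabs <- lapply(reps, computePhenotypes, counts = counts,
                 pseudocount = pseudocount)
  if (length(tabs) == 1L) {
    out <- tabs[[1L]]
    names(out)[names(out) == "phenotype"] <- "phenotype_rep1"
    out$phenotype_mean <- out$phenotype_rep1
    return(out)
  }
  averageReplicates(tabs)
}

#' Gene-level screen scores
#'
#' For each targeted gene, tests the gene's sgRNA mean phenotypes against
#' all non-targeting-control phenotypes with a two-sided Mann-Whitney test
#' ([mannWhitney()], auto mode), averages the top three sgRNAs by absolute
#' phenotype (signed average; all sgRNAs if the gene has fewer than
#' three), and forms the screen score
#' \code{avg_top3_phenotype * -log10(mw_p)}. Ranking ties are broken by
#' \code{sgrna_id} so the scoring is deterministic. Genes with fewer than
#' two sgRNAs are excluded with a warning.
#'
#' @param phen an averaged phenotype table from [screenPhenotypes()] or
#'   [averageReplicates()] (any table with \code{sgrna_id},
#'   \code{gene_id}, \code{is_ntc} and \code{phenotype_mean}).
#' @param minNTC minimum number of NTC sgRNAs required (default 10).
#' @return A data frame with one row per gene: \code{gene_id},
#'   \code{n_sgrnas}, \code{avg_top3_phenotype}, \code{mw_p},
#'   \code{screen_score}, \code{is_pseudo = FALSE}.
#' @export
geneScores <- function(phen, minNTC = 10L) {
  if (is.null(phen$phenotype_mean))
    phen$phenotype_mean <- phen$phenotype
  ntcVals <- phen$phenotype_mean[phen$is_ntc]
  if (length(ntcVals) < minNTC)
    stop("need >= ", minNTC, " NTC sgRNAs (found ", length(ntcVals), ")")
  tgt <- phen[!phen$is_ntc, ]
  .scoreGenes(split(tgt[, c("sgrna_id", "phenotype_mean")], tgt$gene_id),
              ntcVals, is_pseudo = FALSE)
}

# shared scorer for real genes and pseudo-genes; a group may carry an
# $exclude attribute of reference indices to drop (pseudo-genes are built
# from the NTC pool, and keeping their own draws in the reference would
# bias their test toward the null — a real gene's sgRNAs are never part
# of the reference)
.scoreGenes <- function(groups, ntcVals, is_pseudo) {
  small <- vapply(groups, nrow, 0L) < 2L
  if (any(small)) {
    warning("excluding gene(s) with < 2 sgRNAs: ",
            paste(utils::head(names(groups)[small], 5L), collapse = ", "))
    groups <- groups[!small]
  }
  ids <- names(groups)
  n <- vapply(groups, nrow, 0L)
  top3 <- vapply(groups, function(g) {
    ord <- order(-abs(g$phenotype_mean), g$sgrna_id)
    mean(g$phenotype_mean[ord][seq_len(min(3L, nrow(g)))])
  }, 0)
  p <- vapply(groups, function(g) {
    ref <- if (is.null(attr(g, "exclude"))) ntcVals
           else ntcVals[-attr(g, "exclude")]
    mannWhitney(g$phenotype_mean, ref, mode = "auto")$p_two_sided
  }, 0)
  out <- data.frame(gene_id = ids, n_sgrnas = n,
                    avg_top3_phenotype = unname(top3), mw_p = unname(p),
                    screen_score = unname(top3 * -log10(p)),
                    is_pseudo = is_pseudo,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$gene_id), , drop = FALSE]
}

#' Pseudo-gene scores for the empirical-FDR null
#'
#' Assembles pseudo-genes from randomly sampled NTC sgRNA phenotypes
#' (without replacement within a pseudo-gene, with replacement across
#' pseudo-genes) and scores them exactly like real genes; each
#' pseudo-gene's own draws are excluded from its Mann-Whitney reference,
#' mirroring the real-gene comparison in which the tested sgRNAs are
#' never part of the control set. Because
#' pseudo-genes are drawn from the null distribution, the fraction passing
#' any threshold pair estimates the screen's false-positive rate there.
#'
#' @inheritParams geneScores
#' @param nPseudo number of pseudo-genes; defaults to the number of real
#'   genes in \code{phen}.
#' @param sgrnasPerPseudo sgRNAs per pseudo-gene; defaults to the modal
#'   sgRNAs-per-gene of the real genes.
#' @param seed integer seed; the construction is reproducible given it.
#' @return A gene-score data frame with \code{is_pseudo = TRUE} and
#'   gene ids \code{pseudo_0001, ...}.
#' @export
pseudoGeneScores <- function(phen, nPseudo = NULL, sgrnasPerPseudo = NULL,
                             seed = 1L) {
  if (is.null(phen$phenotype_mean))
    phen$phenotype_mean <- phen$phenotype
  ntcVals <- phen$phenotype_mean[phen$is_ntc]
  geneTab <- table(phen$gene_id[!phen$is_ntc])
  if (is.null(nPseudo)) nPseudo <- length(geneTab)
  if (nPseudo <= 0) stop("nPseudo must be positive")
  if (is.null(sgrnasPerPseudo)) {
    cnt <- table(geneTab)
    sgrnasPerPseudo <- as.integer(names(cnt)[which.max(cnt)])
  }
  if (length(ntcVals) < sgrnasPerPseudo)
    stop("fewer NTC sgRNAs than sgrnasPerPseudo")
  set.seed(seed)
  groups <- lapply(seq_len(nPseudo), function(i) {
    idx <- sample.int(length(ntcVals), sgrnasPerPseudo)
    g <- data.frame(sgrna_id = sprintf("ntc_pick_%d", idx),
                    phenotype_mean = ntcVals[idx])
    attr(g, "exclude") <- idx
    g
  })
  names(groups) <- sprintf("pseudo_%04d", seq_len(nPseudo))
  .scoreGenes(groups, ntcVals, is_pseudo = TRUE)
}

#' Call screen hits and estimate the empirical FDR
#'
#' A gene is a hit when \code{mw_p <= pThreshold} and
#' \code{|avg_top3_phenotype| >= effectThreshold}. The defaults mirror a
#' volcano cutoff at \eqn{-\log_{10}(0.05)} and a minimum effect of about
#' 25\% (\code{log2(4/3) ~ 0.415} log2 units). The empirical FDR is the
#' pseudo-gene pass fraction divided by the real-gene pass fraction,
#' clipped to [0, 1]; when no real gene passes (or no pseudo-genes are
#' supplied) it is reported as \code{NA} rather than zero. Positive-
#' phenotype hits are genes whose knockdown decreased invasion, i.e.
#' genes necessary for invasion.
#'
#' @param scores real-gene table from [geneScores()].
#' @param pseudo pseudo-gene table from [pseudoGeneScores()], or
#'   \code{NULL}.
#' @param pThreshold Mann-Whitney p cutoff in (0, 1) (default 0.05).
#' @param effectThreshold non-negative |phenotype| cutoff in log2 units
#'   (default \code{log2(4/3)}, about a 25\% change).
#' @return A list with \code{scores} and \code{pseudo} (each gaining a
#'   logical \code{hit} column) and \code{summary}: \code{n_hits_positive},
#'   \code{n_hits_negative}, \code{empirical_fdr}, and the thresholds.
#' @export
callHits <- function(scores, pseudo = NULL, pThreshold = 0.05,
                     effectThreshold = log2(4 / 3)) {
  if (pThreshold <= 0 || pThreshold >= 1) stop("pThreshold must be in (0,1)")
  if (effectThreshold < 0) stop("effectThreshold must be >= 0")
  pass <- function(tab)
    tab$mw_p <= pThreshold & abs(tab$avg_top3_phenotype) >= effectThreshold
  scores$hit <- pass(scores)
  realFrac <- mean(scores$hit)
  fdr <- NA_real_
  if (!is.null(pseudo) && nrow(pseudo)) {
    pseudo$hit <- pass(pseudo)
    if (realFrac > 0)
      fdr <- min(1, max(0, mean(pseudo$hit) / realFrac))
  }
  list(scores = scores, pseudo = pseudo,
       summary = list(
         n_hits_positive = sum(scores$hit & scores$avg_top3_phenotype > 0),
         n_hits_negative = sum(scores$hit & scores$avg_top3_phenotype < 0),
         empirical_fdr = fdr,
         p_threshold = pThreshold, effect_threshold = effectThreshold))
}

#' Volcano-plot table
#'
#' One row per gene (and pseudo-gene, if supplied): effect size,
#' \code{-log10} Mann-Whitney p, screen score and hit flag, ready for
#' plotting or TSV export.
#'
#' @param scores a hit-called (or raw) gene-score table.
#' @param pseudo optional pseudo-gene table to append.
#' @return A data frame with columns \code{gene_id},
#'   \code{avg_top3_phenotype}, \code{neg_log10_p}, \code{screen_score},
#'   \code{hit}, \code{is_pseudo}.
#' @export
volcanoTable <- function(scores, pseudo = NULL) {
  tab <- rbind(scores, pseudo)
  if (is.null(tab$hit)) tab$hit <- NA
  data.frame(gene_id = tab$gene_id,
             avg_top3_phenotype = tab$avg_top3_phenotype,
             neg_log10_p = -log10(tab$mw_p),
             screen_score = tab$screen_score,
             hit = tab$hit, is_pseudo = tab$is_pseudo,
             stringsAsFactors = FALSE, row.names = NULL)
}
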