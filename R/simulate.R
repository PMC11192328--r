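#' Screen simulation configuration
#'
#' Defaults mirror the screened library's design: 2,307 targeted genes
#' with 10 sgRNAs each plus 247 non-targeting controls, about 1000x
#' read coverage per sgRNA, and two independent replicates. Counts are
#' negative-binomial around log-normal sgRNA abundances; planted hit
#' genes shift their sgRNAs' endpoint means by
#' \code{2^(true_effect * efficacy)}, where the per-sgRNA efficacy
#' multiplier (Beta-distributed, default Beta(5, 2)) models partial
#' knockdown.
#'
#' @param nGenes,sgrnasPerGene,nNTC library composition.
#' @param nHits number of planted hit genes (default 0, a null screen).
#' @param effectRange absolute log2 effect interval for planted hits;
#'   each hit draws |effect| uniformly from it with random sign unless
#'   \code{positiveOnly}.
#' @param positiveOnly plant only positive (invasion-suppressing) effects.
#' @param efficacyShape Beta(a, b) parameters of the per-sgRNA efficacy;
#'   \code{NULL} for perfect knockdown (efficacy identically 1).
#' @param coverage expected reads per sgRNA (default 1000).
#' @param nbDispersion negative-binomial dispersion (variance
#'   \code{mu + disp * mu^2}); 0 gives Poisson counts.
#' @param t0Sdlog log-normal spread of T0 sgRNA abundances.
#' @param nReplicates number of independent screen replicates.
#' @return A config list for [simulateScreen()].
#' @export
screenSimConfig <- function(nGenes = 2307L, sgrnasPerGene = 10L,
                            nNTC = 247L, nHits = 0L,
                            effectRange = c(0.4, 1.5),
                            positiveOnly = FALSE,
                            efficacyShape = c(5, 2),
                            coverage = 1000, nbDispersion = 0.01,
                            t0Sdlog = 0.5, nReplicates = 2L) {
  cfg <- list(nGenes = as.integer(nGenes),
              sgrnasPerGene = as.integer(sgrnasPerGene),
              nNTC = as.integer(nNTC), nHits = as.integer(nHits),
              effectRange = effectRange, positiveOnly = positiveOnly,
              efficacyShape = efficacyShape, coverage = coverage,
              nbDispersion = nbDispersion, t0Sdlog = t0Sdlog,
              nReplicates = as.integer(nReplicates))
  with(cfg, {
    if (nGenes < 1L || sgrnasPerGene < 2L || nNTC < 1L || nReplicates < 1L)
      stop("counts in the screen config must be positive")
    if (nHits > nGenes) stop("nHits exceeds nGenes")
    if (coverage <= 0 || nbDispersion < 0 || t0Sdlog < 0)
      stop("invalid coverage/dispersion/spread")
    if (any(effectRange < 0) || effectRange[2] < effectRange[1])
      stop("effectRange must be a non-negative increasing interval")
  })
  cfg
}

.randomProtospacers <- function(n, len = 20L) {
  draw <- function(k) vapply(seq_len(k), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), "")
  out <- draw(n)
  while (anyDuplicated(out)) {
    dup <- which(duplicated(out))
    out[dup] <- draw(length(dup))
  }
  out
}

.rcounts <- function(n, mu, dispersion) {
  if (dispersion == 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a pooled CRISPRi invasion screen
#'
#' Generates a library, a T0/endpoint count matrix per replicate and the
#' ground truth of planted effects. T0 abundances are log-normal around
#' the configured coverage; a planted gene's sgRNA i multiplies its
#' endpoint mean by \code{2^(true_effect * efficacy_i)}; counts are
#' negative-binomial; replicates are independent given the shared truth.
#' Fully reproducible given the seed.
#'
#' @param cfg a config from [screenSimConfig()].
#' @param seed integer seed.
#' @return A list: \code{library} (\linkS4class{SgrnaLibrary}),
#'   \code{counts} (\linkS4class{ScreenCounts} with T0 and endpoint
#'   samples per replicate) and \code{truth} (data frame \code{gene_id},
#'   \code{true_effect}, \code{is_hit}).
#' @export
simulateScreen <- function(cfg = screenSimConfig(), seed = 1L) {
  set.seed(seed)
  genes <- sprintf("lnc%04d", seq_len(cfg$nGenes))
  geneCol <- c(rep(genes, each = cfg$sgrnasPerGene), rep("NTC", cfg$nNTC))
  ids <- c(sprintf("%s_sg%02d", rep(genes, each = cfg$sgrnasPerGene),
                   rep(seq_len(cfg$sgrnasPerGene), cfg$nGenes)),
           sprintf("ntc_sg%03d", seq_len(cfg$nNTC)))
  lib <- SgrnaLibrary(ids, geneCol,
                      .randomProtospacers(length(ids)), ntcSentinel = "NTC")

  eff <- numeric(cfg$nGenes)
  if (cfg$nHits > 0L) {
    hitIdx <- sample.int(cfg$nGenes, cfg$nHits)
    mag <- stats::runif(cfg$nHits, cfg$effectRange[1], cfg$effectRange[2])
    sgn <- if (cfg$positiveOnly) 1 else sample(c(-1, 1), cfg$nHits,
                                               replace = TRUE)
    eff[hitIdx] <- mag * sgn
  }
  truth <- data.frame(gene_id = genes, true_effect = eff,
                      is_hit = eff != 0, stringsAsFactors = FALSE)

  nSg <- length(ids)
  sgEffect <- c(rep(eff, each = cfg$sgrnasPerGene), rep(0, cfg$nNTC))
  efficacy <- if (is.null(cfg$efficacyShape)) rep(1, nSg)
              else stats::rbeta(nSg, cfg$efficacyShape[1],
                                cfg$efficacyShape[2])
  t0Mean <- stats::rlnorm(nSg,
                          meanlog = log(cfg$coverage) - cfg$t0Sdlog^2 / 2,
                          sdlog = cfg$t0Sdlog)
  endMean <- t0Mean * 2^(sgEffect * efficacy)

  cols <- list(); cond <- character(); repl <- integer()
  for (r in seq_len(cfg$nReplicates)) {
    cols[[paste0("T0_r", r)]] <- .rcounts(nSg, t0Mean, cfg$nbDispersion)
    cols[[paste0("endpoint_r", r)]] <- .rcounts(nSg, endMean,
                                                cfg$nbDispersion)
    cond <- c(cond, "T0", "endpoint"); repl <- c(repl, r, r)
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- ids
  list(library = lib,
       counts = ScreenCounts(mat, lib, condition = cond, replicate = repl),
       truth = truth)
}

#' Simulate an expression cohort with planted correlations and fold
#' changes
#'
#' Draws a target gene and its planted partners from a Gaussian copula
#' achieving the requested Pearson correlations on the log scale, then
#' exponentiates to abundances; planted fold changes multiply cohort B.
#' Unlisted genes are independent noise.
#'
#' @param nGenes,nSamples matrix dimensions (samples split evenly into
#'   cohorts A and B).
#' @param targetR named numeric vector of planted log-scale correlations
#'   with the target gene, values in (-1, 1), names in
#'   \code{gene0001...}-style ids (or any subset you then plant).
#' @param log2fc named numeric vector of planted log2 fold changes
#'   (cohort B over A).
#' @param targetId row name of the target gene (default
#'   \code{"target_lnc"}).
#' @param meanlog,sdlog log-normal abundance location and spread.
#' @param seed integer seed.
#' @return A list: \code{em} (a \linkS4class{GeneExpression} in TPM-like
#'   arbitrary abundance units, cohort labels in \code{colData}) and
#'   \code{truth} (data frame \code{gene_id}, \code{true_r},
#'   \code{true_log2fc}).
#' @export
simulateExpression <- function(nGenes = 1000L, nSamples = 169L,
                               targetR = NULL, log2fc = NULL,
                               targetId = "target_lnc",
                               meanlog = log(10), sdlog = 1, seed = 1L) {
  if (!is.null(targetR) && any(abs(targetR) >= 1))
    stop("planted correlations must lie in (-1, 1)")
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(nGenes))
  unknown <- setdiff(c(names(targetR), names(log2fc)), genes)
  if (length(unknown))
    stop("planted gene(s) not in the matrix: ",
         paste(unknown, collapse = ", "))
  zt <- stats::rnorm(nSamples)
  z <- matrix(stats::rnorm(nGenes * nSamples), nGenes, nSamples,
              dimnames = list(genes, sprintf("s%03d", seq_len(nSamples))))
  for (g in names(targetR)) {
    r <- targetR[[g]]
    z[g, ] <- r * zt + sqrt(1 - r^2) * stats::rnorm(nSamples)
  }
  mat <- rbind(exp(meanlog + sdlog * zt), exp(meanlog + sdlog * z))
  rownames(mat) <- c(targetId, genes)
  cohort <- rep(c("A", "B"), c(ceiling(nSamples / 2),
                               floor(nSamples / 2)))
  for (g in names(log2fc))
    mat[g, cohort == "B"] <- mat[g, cohort == "B"] * 2^log2fc[[g]]
  truth <- data.frame(gene_id = genes,
                      true_r = ifelse(genes %in% names(targetR),
                                      targetR[genes], 0),
                      true_log2fc = ifelse(genes %in% names(log2fc),
                                           log2fc[genes], 0),
                      stringsAsFactors = FALSE, row.names = NULL)
  list(em = GeneExpression(mat, unit = "TPM", cohort = cohort),
       truth = truth)
}

#' Simulate a survival cohort with a piecewise-linear log-hazard
#'
#' Event times are exponential with hazard
#' \code{baselineRate * exp(betaBelow * min(x, knot) + betaAbove *
#' max(x - knot, 0))}; expression x is log-normal (defaults roughly match
#' a glioma cohort's median/IQR). Censoring times are independent
#' exponentials whose rate is calibrated so the expected censored
#' fraction equals \code{censorRate}.
#'
#' @param n cohort size.
#' @param knot,betaBelow,betaAbove spline truth (defaults: knot 2.5 CPM,
#'   hazard ratio 1.99 per CPM below the knot, flat above).
#' @param baselineRate baseline hazard per day.
#' @param censorRate expected censored fraction in [0, 1).
#' @param exprMeanlog,exprSdlog log-normal expression parameters.
#' @param seed integer seed.
#' @return A list: \code{cohort} (data frame \code{time}, \code{event},
#'   \code{expression}) and \code{truth}.
#' @export
simulateSurvival <- function(n = 600L, knot = 2.5,
                             betaBelow = log(1.99), betaAbove = 0,
                             baselineRate = 1 / 500, censorRate = 0.3,
                             exprMeanlog = log(1.65), exprSdlog = 1,
                             seed = 1L) {
  if (baselineRate <= 0) stop("baselineRate must be positive")
  if (censorRate < 0 || censorRate >= 1) stop("censorRate must be in [0,1)")
  set.seed(seed)
  x <- stats::rlnorm(n, exprMeanlog, exprSdlog)
  h <- baselineRate * exp(betaBelow * pmin(x, knot) +
                          betaAbove * pmax(x - knot, 0))
  eventTime <- stats::rexp(n, rate = h)
  if (censorRate == 0) {
    time <- eventTime; event <- rep(1L, n)
  } else {
    # P(C < T) for Exp(c) vs Exp(h_i) is c/(c+h_i); calibrate c
    cRate <- stats::uniroot(function(cc)
      mean(cc / (cc + h)) - censorRate,
      interval = c(1e-12, 1e6 * max(h)))$root
    censTime <- stats::rexp(n, rate = cRate)
    event <- as.integer(eventTime <= censTime)
    time <- pmin(eventTime, censTime)
  }
  list(cohort = data.frame(time = time, event = event, expression = x),
       truth = list(knot = knot, betaBelow = betaBelow,
                    betaAbove = betaAbove, baselineRate = baselineRate,
                    censorRate = censorRate))
}

#' Simulate a qPCR plate
#'
#' Housekeeping Ct values are Normal(18, sd); the target Ct is the
#' housekeeping Ct plus a baseline delta-Ct, minus \code{log2(fold)} in
#' the treated group, plus replicate noise. With zero noise,
#' [ddctKnockdown()] inverts the construction exactly.
#'
#' @param foldChange true relative expression of the treated group
#'   (e.g. 0.5 = 50 percent knockdown); must be positive.
#' @param ctNoiseSd replicate Ct noise (cycles).
#' @param nReplicates wells per group.
#' @param baselineDct control-group target-minus-housekeeping Ct gap.
#' @param seed integer seed.
#' @return A plate data frame for [ddctKnockdown()].
#' @export
simulateQpcr <- function(foldChange = 0.5, ctNoiseSd = 0.2,
                         nReplicates = 3L, baselineDct = 5, seed = 1L) {
  if (foldChange <= 0) stop("foldChange must be positive")
  set.seed(seed)
  grp <- rep(c("control", "treated"), each = nReplicates)
  hk <- stats::rnorm(2 * nReplicates, 18, ctNoiseSd)
  shift <- ifelse(grp == "treated", -log2(foldChange), 0)
  tgt <- hk + baselineDct + shift + stats::rnorm(2 * nReplicates, 0,
                                                 ctNoiseSd)
  data.frame(sample_id = sprintf("%s_w%d", grp,
                                 rep(seq_len(nReplicates), 2)),
             group = grp, target_ct = tgt, housekeeping_ct = hk,
             stringsAsFactors = FALSE)
}
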