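# deterministic unique protospacers: index encoded in base 4 over ACGT
makeProtospacers <- function(n, len = 20L) {
  alphabet <- c("A", "C", "G", "T")
  vapply(seq_len(n) - 1L, function(i) {
    digits <- integer(len)
    for (k in seq_len(len)) {
      digits[k] <- i %% 4L
      i <- i %/% 4L
    }
    paste(alphabet[digits + 1L], collapse = "")
  }, "")
}

# small library: nGenes genes x sgrnasPerGene sgRNAs + nNTC controls
toyLibrary <- function(nGenes = 2L, sgrnasPerGene = 3L, nNTC = 4L) {
  genes <- sprintf("gene%02d", seq_len(nGenes))
  ids <- c(sprintf("%s_sg%d", rep(genes, each = sgrnasPerGene),
                   rep(seq_len(sgrnasPerGene), nGenes)),
           sprintf("ntc_%02d", seq_len(nNTC)))
  SgrnaLibrary(ids,
               c(rep(genes, each = sgrnasPerGene), rep("NTC", nNTC)),
               makeProtospacers(length(ids)))
}

# phenotype table straight from values (bypasses counts)
phenTable <- function(values, geneIds, isNtc) {
  data.frame(sgrna_id = sprintf("sg%03d", seq_along(values)),
             gene_id = geneIds, is_ntc = isNtc,
             phenotype_mean = values, stringsAsFactors = FALSE)
}

# brute-force two-sided Mann-Whitney p over all C(N, nx) labelings,
# using the symmetric deviation |U - nx*ny/2|
mwOracle <- function(x, y) {
  pool <- c(x, y)
  nx <- length(x)
  uOf <- function(idx) {
    xs <- pool[idx]; ys <- pool[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  mu <- nx * length(y) / 2
  devObs <- abs(uOf(seq_len(nx)) - mu)
  labelings <- utils::combn(length(pool), nx)
  devs <- apply(labelings, 2L, function(idx) abs(uOf(idx) - mu))
  mean(devs >= devObs - 1e-9)
}

# brute-force Benjamini-Hochberg step-up
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  run <- 1
  for (k in seq_len(m)) {
    i <- o[k]
    rank <- m - k + 1L
    run <- min(run, p[i] * m / rank)
    adj[i] <- run
  }
  adj
}

# brute-force log-rank chi-square from the 2-group risk tables
logrankOracle <- function(group, time, event) {
  group <- factor(group)
  stopifnot(nlevels(group) == 2L)
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & group == levels(group)[1L])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == levels(group)[1L])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}
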