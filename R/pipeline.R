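#' Run the screen pipeline end to end
#'
#' Orchestrates simulate (or load) -> phenotypes -> gene scores ->
#' pseudo-gene null -> hit calling, writing all tables, a JSON run
#' summary, a manifest echoing the effective configuration, and a
#' timestamped plain-text log into a run directory. Deterministic given
#' the configuration and seed.
#'
#' Recognized configuration keys (a flat YAML file or a list):
#' \describe{
#'   \item{seed}{integer seed for simulation and the pseudo-gene null.}
#'   \item{out}{run directory (created if absent).}
#'   \item{simulate}{list of [screenSimConfig()] arguments; mutually
#'     exclusive with \code{library}/\code{counts}.}
#'   \item{library, counts}{paths to a library TSV and count TSV.}
#'   \item{pseudocount}{phenotype pseudocount (default 1).}
#'   \item{p_threshold, effect_threshold}{hit thresholds (defaults 0.05
#'     and \code{log2(4/3)}).}
#'   \item{n_pseudo}{pseudo-gene count, or \code{"auto"} (one per real
#'     gene).}
#' }
#' Unknown keys are rejected.
#'
#' @param config a named list or path to a YAML file.
#' @return The run summary list, invisibly; on-disk outputs are
#'   \code{library.tsv}, \code{counts.tsv}, \code{gene_scores.tsv},
#'   \code{volcano.tsv}, \code{summary.json}, \code{manifest.json},
#'   \code{log.txt} under \code{config$out}.
#' @export
runScreenPipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  known <- c("seed", "out", "simulate", "library", "counts",
             "pseudocount", "p_threshold", "effect_threshold", "n_pseudo")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$out)) stop("config$out (run directory) is required")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  pc <- if (is.null(config$pseudocount)) 1 else config$pseudocount
  pThr <- if (is.null(config$p_threshold)) 0.05 else config$p_threshold
  eThr <- if (is.null(config$effect_threshold)) log2(4 / 3)
          else config$effect_threshold

  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(config$out, "log.txt")
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    cat(line, "\n", file = logFile, sep = "", append = TRUE)
  }
  cat("", file = logFile)

  stage <- "input"
  result <- tryCatch({
    if (!is.null(config$simulate)) {
      stage <- "simulate"
      note("simulating screen (seed ", seed, ")")
      sim <- do.call(screenSimConfig, as.list(config$simulate))
      simOut <- simulateScreen(sim, seed = seed)
      lib <- simOut$library; counts <- simOut$counts
      utils::write.table(simOut$truth,
                         file.path(config$out, "ground_truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      stage <- "load"
      for (f in c(config$library, config$counts))
        if (!file.exists(f)) stop("input not found: ", f)
      lib <- readSgrnaLibrary(config$library, quiet = TRUE)
      counts <- readScreenCounts(config$counts, lib)
    }
    writeSgrnaLibrary(lib, file.path(config$out, "library.tsv"))
    writeScreenCounts(counts, file.path(config$out, "counts.tsv"))

    stage <- "phenotypes"
    note("computing phenotypes (pseudocount ", pc, ")")
    phen <- screenPhenotypes(counts, pseudocount = pc)

    stage <- "scores"
    note("scoring genes")
    scores <- geneScores(phen)
    nPseudo <- config$n_pseudo
    if (is.null(nPseudo) || identical(nPseudo, "auto")) nPseudo <- NULL
    pseudo <- pseudoGeneScores(phen, nPseudo = nPseudo, seed = seed)

    stage <- "hits"
    called <- callHits(scores, pseudo, pThreshold = pThr,
                      effectThreshold = eThr)
    utils::write.table(called$scores,
                       file.path(config$out, "gene_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(volcanoTable(called$scores, called$pseudo),
                       file.path(config$out, "volcano.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    summary <- c(called$summary,
                 list(n_genes = nrow(scores), n_pseudo = nrow(pseudo),
                      pseudocount = pc, seed = seed))
    jsonlite::write_json(summary, file.path(config$out, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest <- list(config = config,
                     effective = list(seed = seed, pseudocount = pc,
                                      p_threshold = pThr,
                                      effect_threshold = eThr),
                     package_version =
                       as.character(utils::packageVersion("InvasionScreen")))
    jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    note("done: ", summary$n_hits_positive, " positive / ",
         summary$n_hits_negative, " negative hits")
    summary
  }, error = function(e) {
    note("FAILED at stage ", stage, ": ", conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}
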