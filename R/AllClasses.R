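#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- rowData colData rowData<- colData<-
NULL

#' sgRNA library design table
#'
#' An \code{SgrnaLibrary} maps each sgRNA of a pooled CRISPRi library to its
#' target gene and records which sgRNAs are non-targeting controls (NTCs).
#' It is the screen's design object: phenotype normalization, gene scoring
#' and pseudo-gene construction all consult it.
#'
#' The object is a \linkS4class{DFrame} with mandatory columns
#' \code{sgrna_id}, \code{gene_id}, \code{protospacer} and \code{is_ntc},
#' and the NTC sentinel stored in \code{metadata(x)$ntc_sentinel}.
#' Validity requires unique sgRNA identifiers, protospacers over
#' \{A,C,G,T\} of uniform length, \code{is_ntc} exactly where
#' \code{gene_id} equals the sentinel, and at least two sgRNAs per
#' targeted gene (gene scoring needs a within-gene sample).
#'
#' @seealso [readSgrnaLibrary()], [ScreenCounts()]
#' @aliases SgrnaLibrary-class
#' @exportClass SgrnaLibrary
setClass("SgrnaLibrary", contains = "DFrame")

setValidity("SgrnaLibrary", function(object) {
  msg <- character()
  need <- c("sgrna_id", "gene_id", "protospacer", "is_ntc")
  miss <- setdiff(need, colnames(object))
  if (length(miss))
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  dup <- unique(object$sgrna_id[duplicated(object$sgrna_id)])
  if (length(dup))
    msg <- c(msg, paste0("duplicate sgrna_id: ",
                         paste(utils::head(dup, 5L), collapse = ", ")))
  bad <- grepl("[^ACGT]", object$protospacer)
  if (any(bad))
    msg <- c(msg, paste0("non-ACGT protospacer in row(s): ",
                         paste(utils::head(which(bad), 5L), collapse = ", ")))
  if (length(unique(nchar(object$protospacer))) > 1L)
    msg <- c(msg, "protospacer length is not uniform across the library")
  sentinel <- metadata(object)$ntc_sentinel
  if (is.null(sentinel))
    msg <- c(msg, "metadata()$ntc_sentinel is not set")
  else if (!identical(object$is_ntc, object$gene_id == sentinel))
    msg <- c(msg, "is_ntc must be TRUE exactly where gene_id equals the NTC sentinel")
  tab <- table(object$gene_id[!object$is_ntc])
  if (any(tab < 2L))
    msg <- c(msg, paste0("gene(s) with fewer than 2 sgRNAs: ",
                         paste(utils::head(names(tab)[tab < 2L], 5L),
                               collapse = ", ")))
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct an SgrnaLibrary
#'
#' @param sgrna_id character vector of unique sgRNA identifiers.
#' @param gene_id character vector of target gene identifiers; rows whose
#'   \code{gene_id} equals \code{ntcSentinel} are non-targeting controls.
#' @param protospacer character vector of protospacer sequences (A/C/G/T,
#'   uniform length).
#' @param ntcSentinel the \code{gene_id} value marking non-targeting
#'   controls (default \code{"NTC"}).
#' @return A validated \linkS4class{SgrnaLibrary}.
#' @examples
#' lib <- SgrnaLibrary(
#'   sgrna_id = c("g1_1", "g1_2", "ntc_1"),
#'   gene_id = c("GENE1", "GENE1", "NTC"),
#'   protospacer = c("ACGTACGTACGTACGTACGT",
#'                   "TTTTACGTACGTACGTACGT",
#'                   "GGGGACGTACGTACGTACGT"))
#' nGenes(lib)
#' @export
SgrnaLibrary <- function(sgrna_id, gene_id, protospacer, ntcSentinel = "NTC") {
  df <- DataFrame(sgrna_id = as.character(sgrna_id),
                  gene_id = as.character(gene_id),
                  protospacer = toupper(as.character(protospacer)))
  df$is_ntc <- df$gene_id == ntcSentinel
  metadata(df)$ntc_sentinel <- ntcSentinel
  out <- new("SgrnaLibrary", df)
  validObject(out)
  out
}

#' Screen count container
#'
#' A \code{ScreenCounts} object holds the sgRNA-by-sample read-count matrix
#' of a pooled screen together with the library design. It extends
#' \linkS4class{SummarizedExperiment}: the single \code{"counts"} assay is
#' the integer count grid, \code{rowData} carries the library columns and
#' \code{colData} carries per-sample \code{condition}
#' (\code{"T0"} or \code{"endpoint"}), integer \code{replicate}, and a
#' \code{usable} flag that is \code{FALSE} for zero-sum samples.
#'
#' @aliases ScreenCounts-class
#' @seealso [computePhenotypes()], [readScreenCounts()]
#' @exportClass ScreenCounts
setClass("ScreenCounts", contains = "SummarizedExperiment")

setValidity("ScreenCounts", function(object) {
  msg <- character()
  if (!"counts" %in% names(assays(object)))
    return("assay 'counts' is required")
  cnt <- assay(object, "counts")
  if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
  if (any(cnt != round(cnt))) msg <- c(msg, "counts must be integers")
  need <- c("condition", "replicate", "usable")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste("colData missing:", paste(miss, collapse = ", ")))
  else {
    if (!all(object$condition %in% c("T0", "endpoint")))
      msg <- c(msg, "condition must be 'T0' or 'endpoint'")
  }
  rneed <- c("sgrna_id", "gene_id", "is_ntc")
  rmiss <- setdiff(rneed, colnames(rowData(object)))
  if (length(rmiss))
    msg <- c(msg, paste("rowData missing:", paste(rmiss, collapse = ", ")))
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a ScreenCounts object
#'
#' @param counts integer matrix, sgRNAs in rows, samples in columns; row
#'   names must cover exactly the library's sgRNA set.
#' @param library an \linkS4class{SgrnaLibrary}.
#' @param condition character vector per sample: \code{"T0"} or
#'   \code{"endpoint"}.
#' @param replicate integer vector per sample.
#' @return A \linkS4class{ScreenCounts}. Samples whose column sum is zero
#'   are flagged \code{usable = FALSE} with a warning; analysis functions
#'   refuse them.
#' @export
ScreenCounts <- function(counts, library, condition, replicate) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stop("counts must have sgrna_id row names")
  if (!setequal(rownames(counts), sgrnaIds(library)))
    stop("count rows must match the library sgRNA set; orphans: ",
         paste(utils::head(setdiff(rownames(counts), sgrnaIds(library)), 5L),
               collapse = ", "))
  counts <- counts[sgrnaIds(library), , drop = FALSE]
  storage.mode(counts) <- "integer"
  usable <- colSums(counts) > 0
  if (!all(usable))
    warning("zero-sum sample column(s) flagged unusable: ",
            paste(colnames(counts)[!usable], collapse = ", "))
  cd <- DataFrame(condition = as.character(condition),
                  replicate = as.integer(replicate),
                  usable = usable,
                  row.names = colnames(counts))
  se <- SummarizedExperiment(assays = SimpleList(counts = counts),
                             rowData = as(library, "DFrame"), colData = cd)
  metadata(se)$ntc_sentinel <- metadata(library)$ntc_sentinel
  out <- new("ScreenCounts", se)
  validObject(out)
  out
}

#' Gene expression container with coordinates and cohort labels
#'
#' Wraps a gene-by-sample abundance grid (counts, CPM, TPM or RPKM; the
#' unit is recorded in \code{metadata(x)$unit}) as a
#' \linkS4class{SummarizedExperiment}. Optional \code{rowData} columns
#' \code{chromosome}, \code{start}, \code{end} (1-based inclusive),
#' \code{length} (bp) and \code{biotype} (\code{"coding"} or
#' \code{"noncoding"}) feed RPKM normalization, chromosome-subset CPM and
#' coding-only filters; \code{colData$cohort} labels the sample groups.
#'
#' @aliases GeneExpression-class
#' @exportClass GeneExpression
setClass("GeneExpression", contains = "SummarizedExperiment")

setValidity("GeneExpression", function(object) {
  msg <- character()
  if (length(assays(object)) < 1L) return("an assay is required")
  if (any(assay(object) < 0, na.rm = TRUE))
    msg <- c(msg, "abundances must be non-negative")
  if (is.null(metadata(object)$unit))
    msg <- c(msg, "metadata()$unit must record the abundance unit")
  rd <- rowData(object)
  if ("length" %in% colnames(rd) && any(rd$length <= 0, na.rm = TRUE))
    msg <- c(msg, "gene lengths must be positive")
  if (all(c("start", "end") %in% colnames(rd)) &&
      any(rd$end < rd$start, na.rm = TRUE))
    msg <- c(msg, "end must be >= start (1-based inclusive coordinates)")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a GeneExpression object
#'
#' @param abundance numeric gene-by-sample matrix with gene row names.
#' @param unit one of \code{"counts"}, \code{"CPM"}, \code{"TPM"},
#'   \code{"RPKM"}.
#' @param geneInfo optional data frame of per-gene metadata
#'   (\code{chromosome}, \code{start}, \code{end}, \code{length},
#'   \code{biotype}), rows matching the abundance rows.
#' @param cohort optional character vector of per-sample cohort labels.
#' @return A \linkS4class{GeneExpression}.
#' @export
GeneExpression <- function(abundance, unit = c("counts", "CPM", "TPM", "RPKM"),
                           geneInfo = NULL, cohort = NULL) {
  unit <- match.arg(unit)
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)))
    stop("abundance must have gene row names")
  rd <- if (is.null(geneInfo)) DataFrame(row.names = rownames(abundance))
        else DataFrame(geneInfo, row.names = rownames(abundance))
  cd <- DataFrame(row.names = colnames(abundance))
  if (!is.null(cohort)) cd$cohort <- as.character(cohort)
  se <- SummarizedExperiment(assays = SimpleList(abundance = abundance),
                             rowData = rd, colData = cd)
  metadata(se)$unit <- unit
  out <- new("GeneExpression", se)
  validObject(out)
  out
}

#' Piecewise-linear (two-segment spline) Cox model fit
#'
#' Holds a proportional-hazards fit whose log-hazard is piecewise linear in
#' an expression covariate with a single knot: one slope below the knot,
#' another above. Slots carry the knot (CPM), the two log-hazard slopes per
#' 1 CPM with their standard errors, the partial log-likelihood and
#' \eqn{AIC = -2\,\ell + 2k} (k = number of regression coefficients), the
#' cohort size and event count, the tie-handling method, and the underlying
#' \code{\link[survival]{coxph}} object.
#'
#' @aliases SplineCoxFit-class
#' @seealso [coxSplineFit()], [knotSearch()], [hazardRatios()]
#' @exportClass SplineCoxFit
setClass("SplineCoxFit",
  representation(knot = "numeric", beta = "numeric", se = "numeric",
                 loglik = "numeric", aic = "numeric", n = "integer",
                 nEvents = "integer", ties = "character",
                 converged = "logical", coxph = "ANY"))

setValidity("SplineCoxFit", function(object) {
  msg <- character()
  k <- length(object@beta)
  if (length(object@se) != k) msg <- c(msg, "beta and se lengths differ")
  if (abs(object@aic - (-2 * object@loglik + 2 * k)) > 1e-8)
    msg <- c(msg, "aic inconsistent with loglik and parameter count")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
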