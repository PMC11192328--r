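#' @rdname SgrnaLibrary
#' @param x an \linkS4class{SgrnaLibrary} (or \linkS4class{ScreenCounts}
#'   where noted).
#' @export
setGeneric("sgrnaIds", function(x) standardGeneric("sgrnaIds"))

#' @rdname SgrnaLibrary
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname SgrnaLibrary
#' @export
setGeneric("isNTC", function(x) standardGeneric("isNTC"))

#' @rdname SgrnaLibrary
#' @export
setGeneric("protospacers", function(x) standardGeneric("protospacers"))

#' @rdname SgrnaLibrary
#' @export
setGeneric("ntcSentinel", function(x) standardGeneric("ntcSentinel"))

#' @rdname SgrnaLibrary
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname SgrnaLibrary
#' @export
setGeneric("nNTC", function(x) standardGeneric("nNTC"))

#' @rdname GeneExpression
#' @param x a \linkS4class{GeneExpression}.
#' @export
setGeneric("exprUnit", function(x) standardGeneric("exprUnit"))

#' @rdname hazardRatios
#' @export
setGeneric("hazardRatios", function(object, level = 0.95)
  standardGeneric("hazardRatios"))

setMethod("sgrnaIds", "SgrnaLibrary", function(x) x$sgrna_id)
setMethod("geneIds", "SgrnaLibrary",
          function(x) unique(x$gene_id[!x$is_ntc]))
setMethod("isNTC", "SgrnaLibrary", function(x) x$is_ntc)
setMethod("protospacers", "SgrnaLibrary",
          function(x) stats::setNames(x$protospacer, x$sgrna_id))
setMethod("ntcSentinel", "SgrnaLibrary",
          function(x) metadata(x)$ntc_sentinel)
setMethod("nGenes", "SgrnaLibrary", function(x) length(geneIds(x)))
setMethod("nNTC", "SgrnaLibrary", function(x) sum(x$is_ntc))

setMethod("sgrnaIds", "ScreenCounts", function(x) rowData(x)$sgrna_id)
setMethod("isNTC", "ScreenCounts", function(x) rowData(x)$is_ntc)

setMethod("exprUnit", "GeneExpression", function(x) metadata(x)$unit)

setMethod("show", "SgrnaLibrary", function(object) {
  cat(sprintf("SgrnaLibrary: %d sgRNAs | %d genes | %d NTCs (sentinel '%s')\n",
              nrow(object), nGenes(object), nNTC(object),
              ntcSentinel(object)))
  callNextMethod()
})

setMethod("show", "SplineCoxFit", function(object) {
  cat("SplineCoxFit (two-segment linear-spline Cox model)\n")
  cat(sprintf("  knot: %.3g CPM | ties: %s | n = %d, events = %d\n",
              object@knot, object@ties, object@n, object@nEvents))
  hr <- hazardRatios(object)
  for (i in seq_len(nrow(hr)))
    cat(sprintf("  %s: HR %.3f (95%% CI %.3f-%.3f) per 1 CPM\n",
                rownames(hr)[i], hr$hr[i], hr$lower[i], hr$upper[i]))
  cat(sprintf("  loglik = %.3f, AIC = %.3f\n", object@loglik, object@aic))
  invisible(object)
})

#' Hazard ratios of a spline Cox fit
#'
#' @param object a \linkS4class{SplineCoxFit}.
#' @param level confidence level for the Wald interval (default 0.95).
#' @return A data frame with one row per coefficient (\code{below},
#'   \code{above} for the two spline segments, then any adjustment
#'   covariates) and columns \code{beta}, \code{se}, \code{hr},
#'   \code{lower}, \code{upper}, \code{p} (two-sided Wald).
#' @export
setMethod("hazardRatios", "SplineCoxFit", function(object, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- object@beta; s <- object@se
  data.frame(beta = b, se = s, hr = exp(b),
             lower = exp(b - z * s), upper = exp(b + z * s),
             p = 2 * stats::pnorm(-abs(b / s)),
             row.names = names(b))
})
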