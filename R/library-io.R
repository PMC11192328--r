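#' Read an sgRNA library table
#'
#' Reads a tab-separated library file with header columns \code{sgrna_id},
#' \code{gene_id} and \code{protospacer}. Rows whose \code{gene_id} equals
#' the NTC sentinel are flagged as non-targeting controls. Gene and NTC
#' counts are reported via \code{message()}.
#'
#' @param path path to the TSV file.
#' @param ntcSentinel \code{gene_id} value marking non-targeting controls.
#' @param quiet suppress the composition message.
#' @return A validated \linkS4class{SgrnaLibrary}.
#' @export
readSgrnaLibrary <- function(path, ntcSentinel = "NTC", quiet = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sgrna_id", "gene_id", "protospacer")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("library file missing column(s): ", paste(miss, collapse = ", "))
  lib <- SgrnaLibrary(df$sgrna_id, df$gene_id, df$protospacer,
                      ntcSentinel = ntcSentinel)
  if (!quiet)
    message(sprintf("read sgRNA library: %d sgRNAs, %d genes, %d NTCs",
                    nrow(lib), nGenes(lib), nNTC(lib)))
  lib
}

#' Write an sgRNA library table
#'
#' @param library an \linkS4class{SgrnaLibrary}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeSgrnaLibrary <- function(library, path) {
  df <- as.data.frame(library)[, c("sgrna_id", "gene_id", "protospacer")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write screen count matrices
#'
#' The count TSV has an \code{sgrna_id} first column and one column per
#' sample, named \code{<condition>_r<replicate>} (for example
#' \code{T0_r1}, \code{endpoint_r2}); condition and replicate are parsed
#' from the name so that a write/read cycle is lossless. Negative counts
#' are a hard error; sgRNAs absent from the library are reported as
#' orphans; zero-sum sample columns are flagged unusable with a warning.
#'
#' @param path TSV path.
#' @param library the \linkS4class{SgrnaLibrary} the counts belong to.
#' @return \code{readScreenCounts}: a \linkS4class{ScreenCounts}.
#' @export
readScreenCounts <- function(path, library) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (colnames(df)[1L] != "sgrna_id")
    stop("first column of a count file must be sgrna_id")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df$sgrna_id
  if (any(mat < 0)) stop("negative count in ", path)
  orphans <- setdiff(rownames(mat), sgrnaIds(library))
  if (length(orphans))
    stop("sgrna_id absent from library: ",
         paste(utils::head(orphans, 5L), collapse = ", "))
  parsed <- regmatches(colnames(mat),
                       regexec("^(T0|endpoint)_r([0-9]+)$", colnames(mat)))
  bad <- lengths(parsed) != 3L
  if (any(bad))
    stop("sample column name(s) not of the form <T0|endpoint>_r<k>: ",
         paste(colnames(mat)[bad], collapse = ", "))
  ScreenCounts(mat, library,
               condition = vapply(parsed, `[`, "", 2L),
               replicate = as.integer(vapply(parsed, `[`, "", 3L)))
}

#' @rdname readScreenCounts
#' @param counts a \linkS4class{ScreenCounts} to serialize.
#' @return \code{writeScreenCounts}: \code{path}, invisibly.
#' @export
writeScreenCounts <- function(counts, path) {
  mat <- assay(counts, "counts")
  df <- data.frame(sgrna_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count exact protospacer matches in a FASTQ file
#'
#' Assigns each read to an sgRNA by exact substring match of the library
#' protospacer at a fixed 0-based offset; anything else increments the
#' unassigned counter, so assigned + unassigned always equals the read
#' total. No mismatch tolerance, demultiplexing or quality filtering is
#' attempted.
#'
#' @param fastq path to a FASTQ file (gzip accepted).
#' @param library an \linkS4class{SgrnaLibrary} with unique protospacers.
#' @param matchOffset 0-based offset of the protospacer within the read.
#' @param matchLength match length; defaults to the library's protospacer
#'   length.
#' @return A list with \code{counts} (named integer vector over the
#'   library's sgRNAs), \code{unassigned} and \code{total}.
#' @export
countReads <- function(fastq, library, matchOffset = 0L,
                       matchLength = NULL) {
  if (nrow(library) == 0L) stop("empty library")
  proto <- protospacers(library)
  if (anyDuplicated(proto)) stop("protospacers must be unique for counting")
  if (is.null(matchLength)) matchLength <- nchar(proto[[1L]])
  reads <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  counts <- stats::setNames(integer(length(proto)), names(proto))
  unassigned <- 0L
  if (length(reads)) {
    w <- Biostrings::width(reads)
    long <- w >= matchOffset + matchLength
    unassigned <- unassigned + sum(!long)
    if (any(long)) {
      sub <- as.character(Biostrings::subseq(reads[long],
                                             start = matchOffset + 1L,
                                             width = matchLength))
      hit <- match(sub, unname(proto))
      unassigned <- unassigned + sum(is.na(hit))
      tab <- table(factor(names(proto)[hit[!is.na(hit)]],
                          levels = names(proto)))
      counts <- counts + as.integer(tab)
    }
  }
  list(counts = counts, unassigned = as.integer(unassigned),
       total = length(reads))
}
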