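#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom BiocGenerics start end width strand
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges GRangesList seqnames
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqinfo Seqinfo
NULL

#' TranscriptSet: a collection of stranded multi-exon transcript models
#'
#' The central container of the identification pipeline. Each transcript is a
#' set of exons on one contig and strand, carried as a named
#' \link[GenomicRanges]{GRangesList} (1-based, closed intervals, the
#' Bioconductor convention), with per-transcript metadata: \code{gene_id} and
#' \code{source_sample} (the sample an assembled transcript came from; empty
#' for reference annotation). Contig lengths, when known, live in the
#' \code{seqinfo} of the exon ranges.
#'
#' Validity requires, per transcript: at least one exon, all widths positive,
#' a single contig and strand, exons sorted and non-overlapping.
#'
#' @slot exons \code{GRangesList} of exons, names are transcript ids.
#' @slot txData \code{DataFrame} with one row per transcript:
#'   \code{transcript_id}, \code{gene_id}, \code{source_sample}, plus any
#'   columns added downstream (e.g. \code{recurrence}, \code{locus} after
#'   merging).
#' @export
setClass("TranscriptSet",
  representation(exons = "GRangesList", txData = "DataFrame"))

setValidity("TranscriptSet", function(object) {
  ex <- object@exons
  td <- object@txData
  if (length(ex) != nrow(td))
    return("exons and txData disagree on transcript count")
  if (length(ex) == 0L) return(TRUE)
  if (is.null(names(ex)) || anyDuplicated(names(ex)))
    return("exons must be uniquely named by transcript id")
  if (!identical(names(ex), td$transcript_id))
    return("names(exons) must equal txData$transcript_id")
  nEx <- S4Vectors::elementNROWS(ex)
  if (any(nEx == 0L))
    return(paste0("transcript(s) with zero exons: ",
                  paste(names(ex)[nEx == 0L], collapse = ", ")))
  flat <- unlist(ex, use.names = FALSE)
  if (any(BiocGenerics::width(flat) < 1L))
    return("all exons must have width >= 1")
  nChrom <- lengths(unique(S4Vectors::splitAsList(
    as.character(GenomicRanges::seqnames(flat)), rep(seq_along(ex), nEx))))
  if (any(nChrom != 1L)) return("each transcript must lie on one contig")
  nStr <- lengths(unique(S4Vectors::splitAsList(
    as.character(BiocGenerics::strand(flat)), rep(seq_along(ex), nEx))))
  if (any(nStr != 1L)) return("each transcript must have one strand")
  ## sorted, non-overlapping exons within each transcript
  st <- S4Vectors::splitAsList(BiocGenerics::start(flat),
                               rep(seq_along(ex), nEx))
  en <- S4Vectors::splitAsList(BiocGenerics::end(flat),
                               rep(seq_along(ex), nEx))
  bad <- vapply(seq_along(ex), function(i) {
    s <- st[[i]]; e <- en[[i]]
    is.unsorted(s) || (length(s) > 1L && any(s[-1L] <= e[-length(e)]))
  }, logical(1))
  if (any(bad))
    return(paste0("unsorted or overlapping exons in: ",
                  paste(names(ex)[bad], collapse = ", ")))
  TRUE
})

#' Construct a TranscriptSet
#'
#' @param exons named \code{GRangesList} of exons (one element per transcript).
#' @param geneId character vector of gene ids, parallel to \code{exons}.
#' @param sourceSample character vector of sample-of-origin labels (may be
#'   empty strings); recycled if length 1.
#' @return a \linkS4class{TranscriptSet}.
#' @export
TranscriptSet <- function(exons, geneId, sourceSample = "") {
  if (is.null(names(exons))) stop("exons must be named by transcript id")
  n <- length(exons)
  if (length(sourceSample) == 1L) sourceSample <- rep(sourceSample, n)
  ## normalize: sort exons within transcript
  exons <- GenomicRanges::GRangesList(lapply(exons, BiocGenerics::sort))
  td <- S4Vectors::DataFrame(transcript_id = names(exons),
                             gene_id = as.character(geneId),
                             source_sample = as.character(sourceSample))
  rownames(td) <- names(exons)
  new("TranscriptSet", exons = exons, txData = td)
}

#' @describeIn TranscriptSet number of transcripts
#' @param x,object a \code{TranscriptSet}.
#' @export
setMethod("length", "TranscriptSet", function(x) length(x@exons))

#' Accessors for TranscriptSet
#'
#' \code{transcriptIds}, \code{geneIds}, \code{exonsBy} (the exon
#' \code{GRangesList}), \code{txData}, \code{exonicLength} (sum of exon
#' widths), \code{exonCount}, \code{txStrand}, \code{txChrom},
#' \code{transcriptSpan} (one range per transcript) and \code{geneSpans}
#' (union hull per gene).
#'
#' @param x a \linkS4class{TranscriptSet}.
#' @return vectors parallel to transcripts, or \code{GRanges} for the span
#'   accessors.
#' @name TranscriptSet-accessors
NULL

#' @rdname TranscriptSet-accessors
#' @export
transcriptIds <- function(x) x@txData$transcript_id

#' @rdname TranscriptSet-accessors
#' @export
geneIds <- function(x) stats::setNames(x@txData$gene_id, transcriptIds(x))

#' @rdname TranscriptSet-accessors
#' @export
exonsBy <- function(x) x@exons

#' @rdname TranscriptSet-accessors
#' @export
txData <- function(x) x@txData

#' @rdname TranscriptSet-accessors
#' @export
exonicLength <- function(x) {
  stats::setNames(as.numeric(sum(BiocGenerics::width(x@exons))),
                  transcriptIds(x))
}

#' @rdname TranscriptSet-accessors
#' @export
exonCount <- function(x) {
  stats::setNames(S4Vectors::elementNROWS(x@exons), transcriptIds(x))
}

#' @rdname TranscriptSet-accessors
#' @export
txStrand <- function(x) {
  nEx <- S4Vectors::elementNROWS(x@exons)
  flat <- unlist(x@exons, use.names = FALSE)
  first <- cumsum(nEx) - nEx + 1L
  stats::setNames(as.character(BiocGenerics::strand(flat))[first],
                  transcriptIds(x))
}

#' @rdname TranscriptSet-accessors
#' @export
txChrom <- function(x) {
  nEx <- S4Vectors::elementNROWS(x@exons)
  flat <- unlist(x@exons, use.names = FALSE)
  first <- cumsum(nEx) - nEx + 1L
  stats::setNames(as.character(GenomicRanges::seqnames(flat))[first],
                  transcriptIds(x))
}

#' @rdname TranscriptSet-accessors
#' @export
transcriptSpan <- function(x) {
  unlist(range(x@exons), use.names = TRUE)
}

#' @rdname TranscriptSet-accessors
#' @export
geneSpans <- function(x) {
  spans <- transcriptSpan(x)
  gid <- geneIds(x)
  byGene <- S4Vectors::split(spans, gid[names(spans)])
  out <- unlist(range(byGene), use.names = TRUE)
  out[order(names(out))]
}

#' Subset a TranscriptSet by transcript id
#' @param x a \code{TranscriptSet}.
#' @param i character vector of transcript ids (or logical/integer index).
#' @param j,drop,... ignored.
#' @export
setMethod("[", "TranscriptSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    miss <- setdiff(i, transcriptIds(x))
    if (length(miss))
      stop("unknown transcript id(s): ", paste(miss, collapse = ", "))
  }
  new("TranscriptSet", exons = x@exons[i], txData = x@txData[i, , drop = FALSE])
})

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet with", length(object), "transcripts on",
      length(unique(txChrom(object))), "contig(s)\n")
  if (length(object)) {
    cat("  genes:", length(unique(object@txData$gene_id)), "\n")
    extra <- setdiff(colnames(object@txData),
                     c("transcript_id", "gene_id", "source_sample"))
    if (length(extra)) cat("  txData extras:", paste(extra, collapse = ", "), "\n")
  }
})

#' TomNetwork: soft-thresholded co-expression with topological overlap
#'
#' Holds the unsigned adjacency \eqn{a_{ij} = |cor(x_i, x_j)|^\beta} and the
#' topological overlap matrix
#' \deqn{TOM_{ij} = (L_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})}
#' with \eqn{L_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and
#' \eqn{k_i = \sum_{u \ne i} a_{iu}}. Diagonal TOM is 1 by convention.
#' Co-expression partnerships are edges with TOM strictly above the
#' edge threshold (0.1 by default downstream).
#'
#' @slot adjacency numeric matrix of \eqn{a_{ij}} (zero diagonal).
#' @slot tom numeric symmetric matrix in [0, 1].
#' @slot beta the soft-threshold exponent used.
#' @slot dropped ids of zero-variance rows excluded before correlation.
#' @export
setClass("TomNetwork",
  representation(adjacency = "matrix", tom = "matrix", beta = "numeric",
                 dropped = "character"))

setValidity("TomNetwork", function(object) {
  tm <- object@tom
  if (!isTRUE(all.equal(tm, t(tm), tolerance = 1e-8)))
    return("tom must be symmetric")
  if (any(tm < -1e-10 | tm > 1 + 1e-10)) return("tom must lie in [0, 1]")
  if (!identical(dim(object@adjacency), dim(tm)))
    return("adjacency and tom dimensions differ")
  TRUE
})

#' @describeIn TomNetwork node ids
#' @param x,object a \code{TomNetwork}.
#' @export
tomNodes <- function(x) rownames(x@tom)

#' @describeIn TomNetwork the TOM matrix
#' @export
tomMatrix <- function(x) x@tom

#' @describeIn TomNetwork the soft-threshold adjacency matrix
#' @export
tomAdjacency <- function(x) x@adjacency

setMethod("show", "TomNetwork", function(object) {
  n <- nrow(object@tom)
  off <- object@tom[upper.tri(object@tom)]
  cat("TomNetwork:", n, "nodes, beta =", object@beta, "\n")
  if (length(off))
    cat(sprintf("  edges with TOM > 0.1: %d of %d pairs\n",
                sum(off > 0.1), length(off)))
  if (length(object@dropped))
    cat("  zero-variance rows dropped:", length(object@dropped), "\n")
})

#' ContaminationModel: two-classifier filter for intronic-artifact transcripts
#'
#' Wraps the machine-learning contamination step of the identification
#' pipeline: a forest-style classifier (bagged decision trees) and a
#' margin-style classifier (L2-regularized logistic separator) fitted on the
#' assembly features of reference-identical ("=") versus intronic ("i")
#' transcripts. Predictions are \code{"equal_like"} or \code{"intronic_like"};
#' the \code{rule} states how the two classifiers combine
#' (\code{both_agree} default, \code{either}, \code{forest_only},
#' \code{margin_only}).
#'
#' @slot forest list of bagged trees.
#' @slot margin fitted glmnet object (plus feature scaling).
#' @slot rule combination rule.
#' @slot featureNames feature column order expected at prediction time.
#' @slot trainSummary list: class counts and held-out accuracy.
#' @slot fitted logical; prediction refuses to run before fitting.
#' @export
setClass("ContaminationModel",
  representation(forest = "list", margin = "list", rule = "character",
                 featureNames = "character", trainSummary = "list",
                 fitted = "logical"))

setMethod("show", "ContaminationModel", function(object) {
  cat("ContaminationModel (rule:", object@rule, ")\n")
  if (object@fitted) {
    ts <- object@trainSummary
    cat(sprintf("  trained on %d '=' and %d 'i' examples; held-out accuracy %.3f\n",
                ts$n_equal, ts$n_intronic, ts$heldout_accuracy))
  } else cat("  not fitted\n")
})
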