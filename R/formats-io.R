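#' Read a GTF/GFF3 annotation into a TranscriptSet
#'
#' Exon records are grouped by \code{transcript_id} (GFF3: \code{Parent} is
#' accepted as fallback) and sorted. GTF coordinates are 1-based inclusive, as
#' is the internal \code{GRanges} representation, so no conversion happens at
#' this boundary. Strand \code{"."}/\code{"*"} is treated as \code{"+"} with a
#' warning. A \code{transcript} record with no exon lines is rejected with its
#' id.
#'
#' @param path GTF (Ensembl-style attributes) or GFF3 file.
#' @param seqlens optional named vector of contig lengths to attach.
#' @return a \linkS4class{TranscriptSet}.
#' @export
readAnnotation <- function(path, seqlens = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop("parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(gr$type)) stop("parse error in ", path, ": no 'type' column")
  tid <- gr$transcript_id
  if (is.null(tid) && !is.null(gr$Parent))
    tid <- as.character(S4Vectors::unstrsplit(gr$Parent, ","))
  if (is.null(tid)) stop("records carry neither transcript_id nor Parent")
  gid <- gr$gene_id
  if (is.null(gid)) gid <- tid
  isEx <- as.character(gr$type) == "exon"
  isTx <- as.character(gr$type) %in% c("transcript", "mRNA")
  noExon <- setdiff(tid[isTx], tid[isEx])
  if (length(noExon))
    stop("transcript(s) with zero exons: ", paste(noExon, collapse = ", "))
  ex <- gr[isEx]
  tid <- tid[isEx]; gid <- gid[isEx]
  if (anyNA(tid)) stop("exon record(s) without transcript_id")
  if (any(as.character(BiocGenerics::strand(ex)) == "*")) {
    warning("strand '.' treated as '+'")
    BiocGenerics::strand(ex)[as.character(BiocGenerics::strand(ex)) == "*"] <- "+"
  }
  S4Vectors::mcols(ex) <- NULL
  exl <- S4Vectors::split(ex, tid)
  ord <- order(names(exl))
  exl <- exl[ord]
  geneOf <- tapply(gid, tid, function(v) v[1L])[names(exl)]
  ts <- TranscriptSet(GenomicRanges::GRangesList(lapply(exl, BiocGenerics::sort)),
                      geneId = as.character(geneOf))
  if (!is.null(seqlens)) ts <- setContigLengths(ts, seqlens)
  ts
}

#' Attach contig lengths to a TranscriptSet
#'
#' Errors if any exon extends beyond its declared contig length.
#'
#' @param x a \code{TranscriptSet}.
#' @param seqlens named integer vector, contig -> length in bp.
#' @export
setContigLengths <- function(x, seqlens) {
  ex <- x@exons
  flat <- unlist(ex, use.names = FALSE)
  chroms <- unique(as.character(GenomicRanges::seqnames(flat)))
  miss <- setdiff(chroms, names(seqlens))
  if (length(miss)) stop("no length for contig(s): ", paste(miss, collapse = ", "))
  over <- BiocGenerics::end(flat) >
    unname(seqlens[as.character(GenomicRanges::seqnames(flat))])
  if (any(over)) stop("exon(s) extend beyond contig length")
  sl <- seqlens[GenomeInfoDb::seqlevels(ex)]
  GenomeInfoDb::seqlengths(ex) <- sl
  new("TranscriptSet", exons = ex, txData = x@txData)
}

#' Write a TranscriptSet as GTF
#'
#' Emits one \code{transcript} and per-exon \code{exon} records with
#' \code{gene_id}/\code{transcript_id} attributes; re-reading with
#' \code{readAnnotation} round-trips exon coordinates exactly.
#'
#' @param x a \code{TranscriptSet}.
#' @param path output file.
#' @export
writeAnnotation <- function(x, path) {
  ex <- x@exons
  nEx <- S4Vectors::elementNROWS(ex)
  flat <- unlist(ex, use.names = FALSE)
  span <- transcriptSpan(x)
  gid <- geneIds(x)
  fmtAttr <- function(g, t) sprintf('gene_id "%s"; transcript_id "%s";', g, t)
  txLines <- sprintf("%s\tlncscape\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                     as.character(GenomicRanges::seqnames(span)),
                     BiocGenerics::start(span), BiocGenerics::end(span),
                     as.character(BiocGenerics::strand(span)),
                     fmtAttr(gid[names(span)], names(span)))
  exTx <- rep(transcriptIds(x), nEx)
  exLines <- sprintf("%s\tlncscape\texon\t%d\t%d\t.\t%s\t.\t%s",
                     as.character(GenomicRanges::seqnames(flat)),
                     BiocGenerics::start(flat), BiocGenerics::end(flat),
                     as.character(BiocGenerics::strand(flat)),
                     fmtAttr(gid[exTx], exTx))
  ## interleave: transcript line then its exons, transcripts in id order
  ord <- order(transcriptIds(x))
  blocks <- split(exLines, factor(exTx, levels = transcriptIds(x)))
  out <- unlist(lapply(ord, function(i) c(txLines[i], blocks[[i]])),
                use.names = FALSE)
  writeLines(out, path)
  invisible(path)
}

#' Build an expression matrix container
#'
#' Wraps a TPM matrix and per-sample tissue descriptions in a
#' \link[SummarizedExperiment]{SummarizedExperiment} (assay \code{"tpm"};
#' \code{colData} columns \code{tissue} and \code{described}). Samples with an
#' empty tissue description are flagged (\code{described == FALSE}) and are
#' excluded later from tissue-specific calling.
#'
#' @param values non-negative numeric matrix, rows = transcripts/genes,
#'   columns = samples; dimnames required and unique.
#' @param tissue character vector of tissue descriptions parallel to columns
#'   (empty string or NA = undescribed).
#' @return a \code{SummarizedExperiment}.
#' @export
ExpressionMatrix <- function(values, tissue = rep("", ncol(values))) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have row and column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate row id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values))) stop("duplicate sample id(s)")
  if (anyNA(values)) stop("NA values are not allowed")
  if (any(values < 0)) stop("negative expression values")
  tissue <- as.character(tissue)
  tissue[is.na(tissue)] <- ""
  SummarizedExperiment::SummarizedExperiment(
    assays = list(tpm = values),
    colData = S4Vectors::DataFrame(tissue = tissue,
                                   described = nzchar(tissue),
                                   row.names = colnames(values)))
}

#' Read an expression TSV plus sample metadata into an ExpressionMatrix
#'
#' @param path TSV, first column row ids, header sample ids, TPM values.
#' @param metaPath TSV with columns \code{sample_id} and
#'   \code{tissue_description} (may be empty).
#' @return a \code{SummarizedExperiment} (see \code{\link{ExpressionMatrix}}).
#' @export
readExpression <- function(path, metaPath = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate row id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  tissue <- rep("", ncol(m))
  if (!is.null(metaPath)) {
    meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE,
                              colClasses = "character")
    idx <- match(colnames(m), meta$sample_id)
    tissue <- ifelse(is.na(idx), "", meta$tissue_description[idx])
    tissue[is.na(tissue)] <- ""
  }
  ExpressionMatrix(m, tissue)
}

#' The TPM assay of an expression container
#' @param se a SummarizedExperiment built by \code{ExpressionMatrix}.
#' @export
tpm <- function(se) SummarizedExperiment::assay(se, "tpm")

#' Read a BED file of genomic intervals
#'
#' BED6 (or BED3) interval sets, e.g. organelle regions or known ncRNAs.
#'
#' @param path BED file.
#' @return \code{GRanges}.
#' @export
readBed <- function(path) rtracklayer::import(path, format = "BED")

#' Write intervals as BED
#' @param gr \code{GRanges}.
#' @param path output file.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

.hitCols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
              "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
              "e_value", "bit_score")

#' Read a 12-column tabular alignment hit table (outfmt 6)
#'
#' @param path TSV without header in the standard 12-column layout.
#' @return data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{percent_identity}, \code{alignment_length}, ..., \code{e_value},
#'   \code{bit_score}.
#' @export
readHitTable <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 12L) stop("expected 12 columns, got ", ncol(df))
  names(df) <- .hitCols
  if (any(df$e_value < 0)) stop("negative e-value")
  if (any(df$alignment_length < 1)) stop("alignment_length must be >= 1")
  df
}

#' Write a hit table in the 12-column tabular layout
#' @param hits data.frame as returned by \code{readHitTable} (extra columns
#'   dropped; missing positional columns filled with 0).
#' @param path output file.
#' @export
writeHitTable <- function(hits, path) {
  for (cc in .hitCols) if (is.null(hits[[cc]])) hits[[cc]] <- 0
  utils::write.table(hits[, .hitCols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a tabular result deterministically
#'
#' Rows are sorted by the first column, ties broken by the second (and so on,
#' left to right); columns keep their given order. Round-trips losslessly via
#' \code{readTable}.
#'
#' @param records data.frame (zero rows allowed: header-only file).
#' @param path output TSV.
#' @export
writeTable <- function(records, path) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) > 1L)
    records <- records[do.call(order, unname(as.list(records))), , drop = FALSE]
  ok <- tryCatch({
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Read a TSV written by writeTable
#' @param path TSV with header.
#' @export
readTable <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)

#' Spliced transcript sequences from a genome
#'
#' Concatenates exon sequences in genomic order and reverse-complements
#' minus-strand transcripts.
#'
#' @param ts a \code{TranscriptSet}.
#' @param genome named \code{DNAStringSet} of contig sequences.
#' @return \code{DNAStringSet} named by transcript id.
#' @export
transcriptSequences <- function(ts, genome) {
  seqs <- lapply(seq_len(length(ts)), function(i) {
    ex <- ts@exons[[i]]
    chrom <- as.character(GenomicRanges::seqnames(ex))[1L]
    if (!chrom %in% names(genome)) stop("contig absent from genome: ", chrom)
    contig <- genome[[chrom]]
    parts <- lapply(seq_along(ex), function(k)
      Biostrings::subseq(contig, BiocGenerics::start(ex)[k],
                         BiocGenerics::end(ex)[k]))
    s <- do.call(Biostrings::xscat, parts)
    if (as.character(BiocGenerics::strand(ex))[1L] == "-")
      s <- Biostrings::reverseComplement(s)
    s
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- transcriptIds(ts)
  out
}
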