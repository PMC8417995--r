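#' Position weight matrix with background and pseudocount
#'
#' Columns are motif positions, rows the bases A, C, G, T. A pseudocount
#' (default 0.01 per cell, avoiding infinite log-odds) is added before
#' per-column renormalization.
#'
#' @param matrix 4 x width numeric matrix of base probabilities (rows in
#'   A, C, G, T order) or counts.
#' @param id motif id.
#' @param background length-4 base probabilities (default uniform).
#' @param pseudocount added to every cell before normalization (> 0).
#' @return a \code{PWM} object (list with class "PWM").
#' @export
newPWM <- function(matrix, id = "motif", background = rep(0.25, 4),
                   pseudocount = 0.01) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4L) stop("PWM needs 4 rows (A, C, G, T)")
  if (ncol(matrix) < 4L) stop("PWM width must be >= 4")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  m <- matrix + pseudocount
  m <- sweep(m, 2L, colSums(m), "/")
  rownames(m) <- c("A", "C", "G", "T")
  background <- background / sum(background)
  structure(list(id = id, matrix = m, background = background,
                 pseudocount = pseudocount, width = ncol(m)),
            class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
  cat("PWM", x$id, "- width", x$width, "\n")
  invisible(x)
}

#' Reverse complement of a PWM
#' @param pwm a \code{PWM}.
#' @export
reverseComplementPwm <- function(pwm) {
  m <- pwm$matrix[4:1, rev(seq_len(pwm$width)), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  out <- pwm
  out$matrix <- m
  out
}

#' Read motifs from minimal MEME text format
#'
#' Parses the MEME text dialect far enough for motif exchange: the
#' \code{MOTIF <id>} header followed by a \code{letter-probability matrix}
#' block of per-position A/C/G/T probabilities.
#'
#' @param path MEME-format text file.
#' @param pseudocount passed to \code{\link{newPWM}}.
#' @return list of \code{PWM} objects.
#' @export
readMemeMotifs <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\s+", lines)
  if (!length(starts)) stop("no MOTIF blocks in ", path)
  lapply(seq_along(starts), function(i) {
    id <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1L]][2L]
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    hdr <- grep("letter-probability matrix", block)
    if (!length(hdr)) stop("motif ", id, " lacks a letter-probability matrix")
    rows <- list()
    for (ln in block[-seq_len(hdr[1L])]) {
      ln <- trimws(ln)
      if (!nzchar(ln)) { if (length(rows)) break else next }
      vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1L]]))
      if (anyNA(vals) || length(vals) != 4L) break
      rows[[length(rows) + 1L]] <- vals
    }
    if (!length(rows)) stop("motif ", id, ": empty probability matrix")
    newPWM(t(do.call(rbind, rows)), id = id, pseudocount = pseudocount)
  })
}

#' Write motifs in minimal MEME text format
#' @param pwms list of \code{PWM} objects.
#' @param path output file.
#' @export
writeMemeMotifs <- function(pwms, path) {
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "")
  for (p in pwms) {
    out <- c(out, paste("MOTIF", p$id),
             sprintf("letter-probability matrix: alength= 4 w= %d", p$width),
             apply(p$matrix, 2L, function(col)
               paste(sprintf("%.6f", col), collapse = " ")),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Extract the promoter (upstream region) of a transcript
#'
#' The promoter is the \code{length}-bp region upstream of the transcript's
#' 5' end (TSS): on the + strand the genomic window just before the first
#' exon start; on the - strand the window just after the last exon end,
#' reverse-complemented. Truncated at contig boundaries, with the realized
#' length recorded.
#'
#' @param tx a \code{TranscriptSet} of length 1 (or exon \code{GRanges}).
#' @param genome named \code{DNAStringSet} of contig sequences.
#' @param length promoter length in bp (default 3000).
#' @return \code{DNAString} (possibly empty) with attribute
#'   \code{truncated} (logical).
#' @export
extractPromoter <- function(tx, genome, length = 3000L) {
  if (is(tx, "TranscriptSet")) {
    stopifnot(base::length(tx) == 1L)
    tx <- tx@exons[[1L]]
  }
  chrom <- as.character(GenomicRanges::seqnames(tx))[1L]
  if (!chrom %in% names(genome)) stop("contig absent from genome: ", chrom)
  contig <- genome[[chrom]]
  clen <- Biostrings::nchar(contig)
  strand <- as.character(BiocGenerics::strand(tx))[1L]
  if (strand == "-") {
    tss <- max(BiocGenerics::end(tx))          # 5' end on the minus strand
    from <- tss + 1L
    to <- min(clen, tss + length)
    if (from > to) {
      out <- Biostrings::DNAString("")
    } else {
      out <- Biostrings::reverseComplement(
        Biostrings::subseq(contig, from, to))
    }
    got <- max(0L, to - from + 1L)
  } else {
    tss <- min(BiocGenerics::start(tx))
    from <- max(1L, tss - length)
    to <- tss - 1L
    out <- if (from > to) Biostrings::DNAString("")
           else Biostrings::subseq(contig, from, to)
    got <- max(0L, to - from + 1L)
  }
  attr(out, "truncated") <- got < length
  out
}

#' Promoters for every transcript in a set
#' @param ts a \code{TranscriptSet}.
#' @inheritParams extractPromoter
#' @return named \code{DNAStringSet}.
#' @export
extractPromoters <- function(ts, genome, length = 3000L) {
  seqs <- lapply(seq_len(base::length(ts)), function(i)
    extractPromoter(ts@exons[[i]], genome, length))
  names(seqs) <- transcriptIds(ts)
  Biostrings::DNAStringSet(lapply(seqs, function(s) s))
}

## exact null distribution of the discretized log-odds score under the
## background model, by dynamic programming over motif columns
.pwmScoreTable <- function(pwm, bin = 1e-3) {
  lods <- log2(pwm$matrix / pwm$background)   # bits
  ## zero-probability cells (possible at pseudocount 0) are clamped to a
  ## -64-bit floor: far below any hit threshold, keeps the DP table finite
  lods[lods < -64] <- -64
  ilods <- round(lods / bin)
  w <- ncol(ilods)
  lo <- sum(apply(ilods, 2L, min))
  hi <- sum(apply(ilods, 2L, max))
  size <- hi - lo + 1L
  dist <- numeric(size)
  off <- -sum(vapply(seq_len(w), function(j) min(ilods[, j]), numeric(1)))
  ## dist[k] = P(sum of first j column scores == k + lo - 1)
  dist[1L] <- 1
  curLo <- 0L
  for (j in seq_len(w)) {
    newDist <- numeric(size)
    cmin <- min(ilods[, j])
    for (b in 1:4) {
      shift <- ilods[b, j] - cmin
      idx <- seq_len(size - shift)
      newDist[idx + shift] <- newDist[idx + shift] +
        dist[idx] * pwm$background[b]
    }
    dist <- newDist
    curLo <- curLo + cmin
  }
  ## dist[k] = P(score == (k - 1 + lo) * bin); tail p-values:
  tail <- rev(cumsum(rev(dist)))
  list(ilods = ilods, bin = bin, lo = lo, tail = tail)
}

.pwmPvalue <- function(tab, intScore) {
  idx <- intScore - tab$lo + 1L
  idx <- pmin(pmax(idx, 1L), length(tab$tail))
  tab$tail[idx]
}

.scanOneStrand <- function(codes, tab, w) {
  n <- length(codes)
  if (n < w) return(list(score = numeric(0), offset = integer(0)))
  nPos <- n - w + 1L
  acc <- numeric(nPos)
  for (j in seq_len(w)) {
    colScores <- c(tab$ilods[, j], 0)        # 5th entry: N scores 0
    acc <- acc + colScores[codes[j:(j + nPos - 1L)]]
  }
  list(score = acc, offset = seq_len(nPos) - 1L)
}

#' Scan a promoter with a PWM at an exact p-value threshold
#'
#' Scores the log-odds (bits, versus the background model) at every offset on
#' both strands. P-values are exact: the null score distribution under the
#' background is computed by dynamic programming with scores discretized to
#' 1e-3-bit bins, and the reported p is the tail probability of the
#' discretized word score. Hits are positions with p strictly below the
#' threshold, sorted by p ascending. N positions contribute log-odds 0.
#'
#' @param sequence promoter sequence (character or \code{DNAString}) over
#'   A/C/G/T/N.
#' @param pwm a \code{PWM} from \code{\link{newPWM}}.
#' @param threshold p-value threshold (default 1e-6, strict <).
#' @param promoterId id recorded on the hits.
#' @return data.frame \code{promoter_id}, \code{motif_id}, \code{offset}
#'   (0-based start within the given sequence), \code{strand}, \code{score}
#'   (bits), \code{p_value}.
#' @export
scanPwm <- function(sequence, pwm, threshold = 1e-6, promoterId = "promoter") {
  .scanWithTabs(sequence, pwm, .pwmScoreTable(pwm),
                .pwmScoreTable(reverseComplementPwm(pwm)), threshold,
                promoterId)
}

.scanWithTabs <- function(sequence, pwm, tab, rcTab, threshold, promoterId) {
  s <- toupper(as.character(sequence))
  w <- pwm$width
  empty <- data.frame(promoter_id = character(0), motif_id = character(0),
                      offset = integer(0), strand = character(0),
                      score = numeric(0), p_value = numeric(0))
  if (nchar(s) < w) return(empty)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  codes <- match(chars, c("A", "C", "G", "T"))
  codes[is.na(codes)] <- 5L
  if (any(!chars %in% c("A", "C", "G", "T", "N")))
    stop("sequence contains characters outside A/C/G/T/N")
  fwd <- .scanOneStrand(codes, tab, w)
  rev_ <- .scanOneStrand(codes, rcTab, w)
  hits <- data.frame(
    promoter_id = promoterId, motif_id = pwm$id,
    offset = c(fwd$offset, rev_$offset),
    strand = c(rep("+", length(fwd$offset)), rep("-", length(rev_$offset))),
    score = c(fwd$score, rev_$score) * tab$bin,
    p_value = c(.pwmPvalue(tab, fwd$score), .pwmPvalue(rcTab, rev_$score)),
    stringsAsFactors = FALSE)
  hits <- hits[hits$p_value < threshold, , drop = FALSE]
  hits <- hits[order(hits$p_value, hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan many promoters with many motifs
#' @param promoters named \code{DNAStringSet} (or character vector).
#' @param pwms list of \code{PWM}s.
#' @inheritParams scanPwm
#' @return combined hit data.frame (see \code{\link{scanPwm}}).
#' @export
scanPromoters <- function(promoters, pwms, threshold = 1e-6) {
  if (inherits(pwms, "PWM")) pwms <- list(pwms)
  out <- list()
  for (p in pwms) {
    tab <- .pwmScoreTable(p)
    rcTab <- .pwmScoreTable(reverseComplementPwm(p))
    for (i in seq_along(promoters)) {
      out[[length(out) + 1L]] <-
        .scanWithTabs(as.character(promoters[[i]]), p, tab, rcTab, threshold,
                      names(promoters)[i])
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(promoter_id = character(0), motif_id = character(0),
                      offset = integer(0), strand = character(0),
                      score = numeric(0), p_value = numeric(0))
  res
}

## best hit per query: lowest e-value, ties by highest bit score then
## lexicographic subject id
.bestHits <- function(hits) {
  o <- order(hits$query_id, hits$e_value, -hits$bit_score, hits$subject_id)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

.rankedHits <- function(hits) {
  o <- order(hits$query_id, hits$e_value, -hits$bit_score, hits$subject_id)
  h <- hits[o, , drop = FALSE]
  h$rank <- stats::ave(seq_len(nrow(h)), h$query_id, FUN = seq_along)
  h
}

## mode of log10(e-value) located with a Freedman-Diaconis histogram;
## e-values of 0 mapped to 1e-200
.evaluePeak <- function(evalues) {
  le <- log10(pmax(evalues, 1e-200))
  if (length(le) < 2L || diff(range(le)) == 0) return(10^le[1L])
  iqr <- stats::IQR(le)
  bw <- if (iqr > 0) 2 * iqr / length(le)^(1 / 3) else diff(range(le)) / 10
  breaks <- seq(min(le), max(le) + bw, by = bw)
  h <- graphics::hist(le, breaks = breaks, plot = FALSE)
  10^h$mids[which.max(h$counts)]
}

#' Two-tier reciprocal-best-hit orthologs
#'
#' Primary tier: mutual best hits between the two hit tables (best hit per
#' query = lowest e-value, ties broken by higher bit score then
#' lexicographically smaller subject id). Secondary tier: pairs ranked 2nd or
#' 3rd among a query's forward hits whose e-value is strictly below the peak
#' (mode) of the distribution of all best-hit e-values, the peak being
#' located as the mode of log10(e-value) under a Freedman-Diaconis histogram
#' (e-values of 0 mapped to 1e-200). Output is sorted by tier then forward
#' e-value.
#'
#' @param hitsAB,hitsBA hit tables (see \code{\link{readHitTable}}) for the
#'   A -> B and B -> A searches.
#' @param secondary logical; include the secondary tier (default TRUE).
#' @return data.frame \code{id_a}, \code{id_b}, \code{e_forward},
#'   \code{e_reverse}, \code{rank_forward}, \code{tier}.
#' @export
rbhOrthologs <- function(hitsAB, hitsBA, secondary = TRUE) {
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      e_forward = numeric(0), e_reverse = numeric(0),
                      rank_forward = integer(0), tier = character(0))
  if (is.null(hitsAB) || !nrow(hitsAB) || is.null(hitsBA) || !nrow(hitsBA))
    return(empty)
  bestAB <- .bestHits(hitsAB)
  bestBA <- .bestHits(hitsBA)
  revBest <- stats::setNames(bestBA$subject_id, bestBA$query_id)
  revE <- stats::setNames(bestBA$e_value, bestBA$query_id)
  mutual <- !is.na(revBest[bestAB$subject_id]) &
    revBest[bestAB$subject_id] == bestAB$query_id
  primary <- data.frame(id_a = bestAB$query_id[mutual],
                        id_b = bestAB$subject_id[mutual],
                        e_forward = bestAB$e_value[mutual],
                        e_reverse = unname(revE[bestAB$subject_id[mutual]]),
                        rank_forward = 1L, tier = "primary",
                        stringsAsFactors = FALSE)
  out <- primary
  if (secondary) {
    peak <- .evaluePeak(c(bestAB$e_value, bestBA$e_value))
    ranked <- .rankedHits(hitsAB)
    cand <- ranked[ranked$rank %in% c(2L, 3L) & ranked$e_value < peak &
                     ranked$query_id %in% primary$id_a, , drop = FALSE]
    if (nrow(cand)) {
      key <- paste(cand$query_id, cand$subject_id)
      pkey <- paste(primary$id_a, primary$id_b)
      cand <- cand[!key %in% pkey, , drop = FALSE]
    }
    if (nrow(cand)) {
      sec <- data.frame(id_a = cand$query_id, id_b = cand$subject_id,
                        e_forward = cand$e_value,
                        e_reverse = NA_real_,
                        rank_forward = as.integer(cand$rank),
                        tier = "secondary", stringsAsFactors = FALSE)
      out <- rbind(primary, sec)
    }
  }
  out <- out[order(match(out$tier, c("primary", "secondary")),
                   out$e_forward, out$id_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}
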