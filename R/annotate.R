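#' Tissue-specificity index Tau
#'
#' \deqn{\tau = \sum_i (1 - x_i / \max(x)) / (N - 1)}
#' Tau is 0 for a constant profile, 1 when exactly one entry is nonzero, and
#' is invariant to scaling the profile by a positive constant. An all-zero
#' profile is undefined and returns \code{NA} (such rows are excluded from
#' tissue-specific calling).
#'
#' @param profile non-negative numeric vector over samples/tissues, length
#'   >= 2.
#' @return Tau in [0, 1], or NA for an all-zero profile.
#' @export
computeTau <- function(profile) {
  if (length(profile) < 2L) stop("profile must have length >= 2")
  if (any(profile < 0)) stop("profile must be non-negative")
  mx <- max(profile)
  if (mx == 0) return(NA_real_)
  sum(1 - profile / mx) / (length(profile) - 1L)
}

#' Per-sample tissue specificity index (TSI)
#'
#' \eqn{tsi_i = x_i / \sum x}; the argmax sample names the specific sample.
#' Ties on the maximum resolve to the lexicographically smallest sample id
#' and are flagged.
#'
#' @param profile non-negative numeric vector with names (sample ids).
#' @return list with \code{tsi} (fractions summing to 1), \code{top_sample},
#'   \code{top_tsi} and \code{tie} (logical).
#' @export
computeTsi <- function(profile) {
  if (is.null(names(profile))) names(profile) <- seq_along(profile)
  tot <- sum(profile)
  if (tot <= 0) return(list(tsi = NULL, top_sample = NA_character_,
                            top_tsi = NA_real_, tie = FALSE))
  tsi <- profile / tot
  topVal <- max(tsi)
  tops <- sort(names(tsi)[tsi == topVal])
  list(tsi = tsi, top_sample = tops[1L], top_tsi = unname(topVal),
       tie = length(tops) > 1L)
}

#' Call tissue-specific lncRNAs
#'
#' Samples lacking a tissue description are excluded first. Each row with
#' Tau strictly greater than the threshold is annotated with the tissue
#' description of its top-TSI sample.
#'
#' @param expr expression container (see \code{\link{ExpressionMatrix}}).
#' @param tauThreshold call threshold, default 0.95 (strict >).
#' @param rowIds optional subset of rows to score (default all).
#' @return data.frame with one row per scored transcript: \code{lncrna_id},
#'   \code{tau}, \code{top_sample}, \code{top_tsi}, \code{tie},
#'   \code{specific} (logical) and \code{tissue} (empty when not called).
#' @export
callTissueSpecific <- function(expr, tauThreshold = 0.95, rowIds = NULL) {
  cd <- SummarizedExperiment::colData(expr)
  keep <- cd$described
  if (sum(keep) < 2L) {
    warning("fewer than 2 described samples; no tissue-specific calls")
    return(data.frame(lncrna_id = character(0), tau = numeric(0),
                      top_sample = character(0), top_tsi = numeric(0),
                      tie = logical(0), specific = logical(0),
                      tissue = character(0)))
  }
  m <- tpm(expr)[, keep, drop = FALSE]
  tissues <- stats::setNames(cd$tissue[keep], rownames(cd)[keep])
  if (is.null(rowIds)) rowIds <- rownames(m)
  res <- lapply(rowIds, function(id) {
    x <- m[id, ]
    tau <- computeTau(x)
    if (is.na(tau))
      return(data.frame(lncrna_id = id, tau = NA_real_,
                        top_sample = NA_character_, top_tsi = NA_real_,
                        tie = FALSE, specific = FALSE, tissue = "",
                        stringsAsFactors = FALSE))
    ts <- computeTsi(x)
    specific <- tau > tauThreshold
    data.frame(lncrna_id = id, tau = tau, top_sample = ts$top_sample,
               top_tsi = ts$top_tsi, tie = ts$tie, specific = specific,
               tissue = if (specific) unname(tissues[ts$top_sample]) else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Adjacent coding genes of lncRNAs
#'
#' For each lncRNA, every reference gene whose span lies strictly closer than
#' \code{window} bp is reported (distance 0 when the spans overlap, else the
#' gap between nearest span ends; strand-agnostic), sorted by distance with
#' the nearest gene(s) flagged.
#'
#' @param lncrna a \code{TranscriptSet} of lncRNAs.
#' @param reference the genome annotation \code{TranscriptSet}.
#' @param window distance cut-off in bp (default 100,000; strict <).
#' @return data.frame \code{lncrna_id}, \code{gene_id}, \code{distance},
#'   \code{nearest}.
#' @export
annotateAdjacentGenes <- function(lncrna, reference, window = 100000) {
  genes <- geneSpans(reference)
  spans <- transcriptSpan(lncrna)
  out <- lapply(seq_along(spans), function(i) {
    d <- suppressWarnings(GenomicRanges::distance(spans[i], genes,
                                                  ignore.strand = TRUE))
    keep <- which(!is.na(d) & d < window)
    if (!length(keep)) return(NULL)
    ord <- keep[order(d[keep], names(genes)[keep])]
    data.frame(lncrna_id = names(spans)[i], gene_id = names(genes)[ord],
               distance = d[ord], nearest = d[ord] == min(d[keep]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(lncrna_id = character(0), gene_id = character(0),
                      distance = numeric(0), nearest = logical(0))
  out
}

#' Build a topological overlap co-expression network
#'
#' Unsigned Pearson adjacency \eqn{a_{ij} = |cor(x_i, x_j)|^\beta} with the
#' topological overlap transform (see \linkS4class{TomNetwork}). Rows with
#' zero variance are excluded and logged on the returned object.
#'
#' @param mat numeric matrix, rows = transcripts/genes, columns = samples
#'   (>= 4).
#' @param beta soft-threshold exponent (default 6, the unsigned-network
#'   convention).
#' @return a \linkS4class{TomNetwork}.
#' @export
buildTom <- function(mat, beta = 6) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 4L) stop("need at least 4 samples")
  v <- apply(mat, 1L, stats::var)
  dropped <- rownames(mat)[v == 0]
  mat <- mat[v > 0, , drop = FALSE]
  if (nrow(mat) < 2L) stop("fewer than 2 variable rows")
  a <- abs(stats::cor(t(mat)))^beta
  diag(a) <- 0
  k <- rowSums(a)
  L <- a %*% a                       # diag(a)=0 already excludes u = i, j
  n <- nrow(a)
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2          # enforce exact symmetry
  dimnames(tom) <- dimnames(a)
  new("TomNetwork", adjacency = a, tom = tom, beta = beta,
      dropped = as.character(dropped))
}

#' Co-expression partners of a node
#'
#' Partners with TOM strictly greater than the threshold, sorted by weight
#' descending.
#'
#' @param tomNet a \linkS4class{TomNetwork}.
#' @param id node id.
#' @param threshold edge threshold (default 0.1, strict >).
#' @return named numeric vector of TOM weights (possibly empty).
#' @export
coexpressionPartners <- function(tomNet, id, threshold = 0.1) {
  tm <- tomMatrix(tomNet)
  if (!id %in% rownames(tm)) stop("unknown id: ", id)
  w <- tm[id, ]
  w <- w[names(w) != id & w > threshold]
  sort(w, decreasing = TRUE)
}

## weighted Kolmogorov-Smirnov running-sum enrichment score (weight p = 1)
.gseaES <- function(rankedWeights, inSet) {
  nr <- sum(abs(rankedWeights[inSet]))
  nMiss <- length(rankedWeights) - sum(inSet)
  if (nr == 0 || nMiss == 0) return(0)
  steps <- ifelse(inSet, abs(rankedWeights) / nr, -1 / nMiss)
  run <- cumsum(steps)
  run[which.max(abs(run))]
}

## ES for a permutation given sorted hit positions (same statistic, O(k))
.gseaESPositions <- function(absW, N, pos) {
  pos <- sort(pos)
  k <- length(pos)
  w <- absW[pos]
  nr <- sum(w)
  if (nr == 0) return(0)
  miss <- 1 / (N - k)
  cumw <- cumsum(w) / nr
  atHit <- cumw - (pos - seq_len(k)) * miss
  beforeHit <- c(0, cumw[-k]) - (pos - seq_len(k)) * miss
  cand <- c(atHit, beforeHit)
  cand[which.max(abs(cand))]
}

#' Annotate a lncRNA by gene-set enrichment of its co-expression ranking
#'
#' All genes are ranked by their TOM weight with the lncRNA; each gene set is
#' scored with the weighted Kolmogorov-Smirnov running-sum enrichment score
#' (weight exponent 1 on the ranking metric). Significance is by gene-label
#' permutation, \eqn{p = (1 + \#\{ES_{perm} \ge ES\}) / (n_{perm} + 1)} for
#' positive enrichment (mirrored for negative), with Benjamini-Hochberg
#' adjustment across the sets tested for this lncRNA. Sets with fewer than 5
#' or more than 500 members in the ranked universe are skipped.
#'
#' @param ranking named numeric vector: gene -> ranking metric (e.g. the TOM
#'   row of the lncRNA over all coding genes).
#' @param geneSets named list of character vectors (GO term -> genes).
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed.
#' @param minSize,maxSize gene-set size window in the universe (5, 500).
#' @return data.frame \code{term_id}, \code{size}, \code{es}, \code{nes},
#'   \code{p}, \code{padj}, ordered by \code{p}.
#' @export
gseaAnnotate <- function(ranking, geneSets, nPerm = 1000L, seed = 1L,
                         minSize = 5L, maxSize = 500L) {
  if (!length(ranking)) stop("empty ranked universe")
  ord <- order(-ranking, names(ranking))
  ranked <- ranking[ord]
  universe <- names(ranked)
  N <- length(universe)
  absW <- abs(ranked)
  set.seed(seed)
  rows <- lapply(names(geneSets), function(term) {
    members <- intersect(geneSets[[term]], universe)
    k <- length(members)
    if (k < minSize || k > maxSize) return(NULL)
    inSet <- universe %in% members
    es <- .gseaES(ranked, inSet)
    perm <- vapply(seq_len(nPerm), function(b)
      .gseaESPositions(absW, N, sample.int(N, k)), numeric(1))
    ## two-sided permutation p on |ES|: calibrated under the null
    p <- (1 + sum(abs(perm) >= abs(es))) / (nPerm + 1)
    denom <- if (es >= 0) mean(perm[perm > 0]) else mean(abs(perm[perm < 0]))
    nes <- if (is.finite(denom) && denom > 0) es / denom else NA_real_
    data.frame(term_id = term, size = k, es = es, nes = nes, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    return(data.frame(term_id = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0), p = numeric(0),
                      padj = numeric(0)))
  rows$padj <- stats::p.adjust(rows$p, method = "BH")
  rows[order(rows$p, rows$term_id), , drop = FALSE]
}

#' Combine the three annotation channels
#'
#' Union semantics: a lncRNA is annotated iff at least one channel is
#' non-empty for it. The summary reports per-channel counts and percentages,
#' the three-way Venn cells, and the overall annotated percentage (rounded to
#' 2 decimals).
#'
#' @param universe character vector of all lncRNA ids.
#' @param tissue data.frame from \code{\link{callTissueSpecific}} (or NULL).
#' @param adjacent data.frame from \code{\link{annotateAdjacentGenes}} (or
#'   NULL).
#' @param coexpression data.frame with at least \code{lncrna_id} rows for
#'   lncRNAs with significant enrichment (or NULL).
#' @return list with \code{records} (one row per lncRNA: channel contents and
#'   \code{channels_used}) and \code{summary} (counts, Venn cells,
#'   percentages), plus the per-channel inputs under \code{channels} for
#'   downstream keyword mining.
#' @export
combineAnnotations <- function(universe, tissue = NULL, adjacent = NULL,
                               coexpression = NULL) {
  idsT <- if (!is.null(tissue))
    unique(tissue$lncrna_id[tissue$specific]) else character(0)
  idsA <- if (!is.null(adjacent))
    unique(adjacent$lncrna_id) else character(0)
  idsC <- if (!is.null(coexpression))
    unique(coexpression$lncrna_id) else character(0)
  idsT <- intersect(idsT, universe)
  idsA <- intersect(idsA, universe)
  idsC <- intersect(idsC, universe)
  inT <- universe %in% idsT
  inA <- universe %in% idsA
  inC <- universe %in% idsC
  tissueOf <- if (!is.null(tissue))
    stats::setNames(tissue$tissue, tissue$lncrna_id) else character(0)
  channels <- ifelse(inT, "tissue", "")
  channels <- paste(channels, ifelse(inA, "adjacent", ""),
                    ifelse(inC, "coexpression", ""), sep = ",")
  channels <- gsub("^,+|,+$", "", gsub(",+", ",", channels))
  records <- data.frame(
    lncrna_id = universe,
    tissue_annotation = ifelse(inT, unname(tissueOf[universe]), ""),
    n_adjacent = as.integer(table(factor(
      if (!is.null(adjacent)) adjacent$lncrna_id else character(0),
      levels = universe))),
    coexpression_annotated = inC,
    channels_used = channels,
    stringsAsFactors = FALSE)
  annotated <- inT | inA | inC
  venn <- c(tissue_only = sum(inT & !inA & !inC),
            adjacent_only = sum(!inT & inA & !inC),
            coexpression_only = sum(!inT & !inA & inC),
            tissue_adjacent = sum(inT & inA & !inC),
            tissue_coexpression = sum(inT & !inA & inC),
            adjacent_coexpression = sum(!inT & inA & inC),
            all_three = sum(inT & inA & inC))
  n <- length(universe)
  pct <- function(x) if (n > 0) percentOf(x, n) else 0
  summary <- list(
    n_total = n,
    n_tissue = sum(inT), percent_tissue = pct(sum(inT)),
    n_adjacent = sum(inA), percent_adjacent = pct(sum(inA)),
    n_coexpression = sum(inC),
    percent_coexpression = pct(sum(inC)),
    n_annotated = sum(annotated),
    percent_annotated = pct(sum(annotated)),
    venn = venn)
  list(records = records, summary = summary,
       channels = list(tissue = tissue, adjacent = adjacent,
                       coexpression = coexpression))
}
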