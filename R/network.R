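#' Select pathway-related lncRNAs by keyword query
#'
#' A lncRNA matches iff any searched channel contains any query term:
#' case-insensitive substring matching on free text (tissue descriptions,
#' term names, gene ids), exact matching on GO ids (terms of the form
#' \code{GO:\\d+}). Adding terms never shrinks the result.
#'
#' @param annotations output of \code{\link{combineAnnotations}}.
#' @param terms character vector of query terms (non-empty).
#' @param channels channels to search, subset of
#'   \code{c("tissue", "adjacent", "coexpression")}.
#' @param goTable optional named list gene -> GO ids, used to match GO-id
#'   terms through the adjacent-gene channel.
#' @param termNames optional named character vector GO id -> term name, used
#'   for substring matches against enrichment results.
#' @return character vector of selected lncRNA ids (sorted).
#' @export
selectRelated <- function(annotations, terms,
                          channels = c("tissue", "adjacent", "coexpression"),
                          goTable = NULL, termNames = NULL) {
  stopifnot(length(terms) >= 1L)
  channels <- intersect(channels, c("tissue", "adjacent", "coexpression"))
  if (!length(channels)) return(character(0))
  isGo <- grepl("^GO:\\d+$", terms)
  goTerms <- terms[isGo]
  txtTerms <- tolower(terms[!isGo])
  ch <- annotations$channels
  hitText <- function(text) {
    if (!length(txtTerms)) return(rep(FALSE, length(text)))
    Reduce(`|`, lapply(txtTerms, function(tt)
      grepl(tt, tolower(text), fixed = TRUE)))
  }
  selected <- character(0)
  if ("tissue" %in% channels && !is.null(ch$tissue)) {
    tdf <- ch$tissue[ch$tissue$specific, , drop = FALSE]
    selected <- c(selected, tdf$lncrna_id[hitText(tdf$tissue)])
  }
  if ("adjacent" %in% channels && !is.null(ch$adjacent)) {
    adf <- ch$adjacent
    hit <- hitText(adf$gene_id)
    if (length(goTerms) && !is.null(goTable)) {
      gos <- goTable[adf$gene_id]
      hit <- hit | vapply(gos, function(g)
        !is.null(g) && any(g %in% goTerms), logical(1))
    }
    selected <- c(selected, adf$lncrna_id[hit])
  }
  if ("coexpression" %in% channels && !is.null(ch$coexpression)) {
    cdf <- ch$coexpression
    hit <- rep(FALSE, nrow(cdf))
    if (!is.null(cdf$term_id) && length(goTerms))
      hit <- hit | cdf$term_id %in% goTerms
    if (!is.null(cdf$term_id) && !is.null(termNames))
      hit <- hit | hitText(ifelse(is.na(termNames[cdf$term_id]), "",
                                  termNames[cdf$term_id]))
    if (!is.null(cdf$term_name)) hit <- hit | hitText(cdf$term_name)
    selected <- c(selected, cdf$lncrna_id[hit])
  }
  sort(unique(selected))
}

#' Bipartite lncRNA-coding gene network from TOM weights
#'
#' All (lncRNA, coding gene) pairs with TOM strictly greater than the
#' threshold, reported with the unique partner-gene count and pair count.
#'
#' @param lncrnaIds selected lncRNA ids (must be nodes of \code{tomNet}).
#' @param tomNet a \linkS4class{TomNetwork} over lncRNAs and genes.
#' @param geneIds coding-gene node ids.
#' @param threshold edge threshold, default 0.1 (strict >).
#' @return list with \code{edges} (data.frame \code{lncrna_id},
#'   \code{gene_id}, \code{weight}), \code{n_genes}, \code{n_pairs}.
#' @export
buildBipartiteNetwork <- function(lncrnaIds, tomNet, geneIds,
                                  threshold = 0.1) {
  tm <- tomMatrix(tomNet)
  lncrnaIds <- intersect(lncrnaIds, rownames(tm))
  geneIds <- intersect(geneIds, colnames(tm))
  edges <- NULL
  if (length(lncrnaIds) && length(geneIds)) {
    sub <- tm[lncrnaIds, geneIds, drop = FALSE]
    idx <- which(sub > threshold, arr.ind = TRUE)
    if (nrow(idx))
      edges <- data.frame(lncrna_id = rownames(sub)[idx[, 1L]],
                          gene_id = colnames(sub)[idx[, 2L]],
                          weight = sub[idx], stringsAsFactors = FALSE)
  }
  if (is.null(edges))
    edges <- data.frame(lncrna_id = character(0), gene_id = character(0),
                        weight = numeric(0))
  edges <- edges[order(-edges$weight, edges$lncrna_id, edges$gene_id), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges, n_genes = length(unique(edges$gene_id)),
       n_pairs = nrow(edges))
}

#' Z-score an expression profile over ordered conditions
#'
#' Centers to mean 0 and scales to unit sample standard deviation (n - 1
#' denominator). Constant profiles are undefined and return NULL.
#'
#' @param values numeric vector over >= 3 ordered conditions.
#' @return z-scored vector, or NULL for constant input.
#' @export
scaleProfile <- function(values) {
  if (length(values) < 3L) stop("need at least 3 conditions")
  s <- stats::sd(values)
  if (s == 0) return(NULL)
  (values - mean(values)) / s
}

#' Z-score the rows of a profile matrix, excluding constant rows
#'
#' @param mat numeric matrix, rows = transcripts, columns = ordered
#'   conditions.
#' @return list with \code{scaled} (matrix of surviving rows) and
#'   \code{excluded} (ids of constant rows).
#' @export
scaleProfiles <- function(mat) {
  mat <- as.matrix(mat)
  sds <- apply(mat, 1L, stats::sd)
  excluded <- rownames(mat)[sds == 0]
  keep <- mat[sds > 0, , drop = FALSE]
  scaled <- (keep - rowMeans(keep)) / apply(keep, 1L, stats::sd)
  list(scaled = scaled, excluded = as.character(excluded))
}

#' Cluster scaled expression patterns
#'
#' k-means with a fixed seed and 10 restarts; clusters are renumbered by
#' descending size (ties by original label) so labels are reproducible.
#'
#' @param scaled matrix of z-scored profiles (rows = objects).
#' @param k number of clusters (default 12).
#' @param seed integer seed.
#' @return list with \code{labels} (named integer vector) and
#'   \code{centers} (k x conditions matrix, renumbered).
#' @export
clusterPatterns <- function(scaled, k = 12L, seed = 1L) {
  scaled <- as.matrix(scaled)
  if (nrow(scaled) < k)
    stop("only ", nrow(scaled), " profiles for k = ", k,
         "; choose a smaller k")
  set.seed(seed)
  km <- stats::kmeans(scaled, centers = k, nstart = 10L, iter.max = 100L)
  sizes <- table(factor(km$cluster, levels = seq_len(k)))
  remap <- order(-as.integer(sizes), seq_len(k))
  newLabel <- match(km$cluster, remap)
  list(labels = stats::setNames(newLabel, rownames(scaled)),
       centers = km$centers[remap, , drop = FALSE])
}

#' Scan for negatively correlated lncRNA-gene expression pairs
#'
#' Pearson correlation on z-scored profiles; pairs with r at or below the
#' threshold are reported sorted ascending by r.
#'
#' @param lncScaled,geneScaled z-scored profile matrices on identical ordered
#'   conditions.
#' @param rThreshold report threshold (default -0.8; \code{r <= rThreshold}).
#' @return data.frame \code{lncrna_id}, \code{gene_id}, \code{r}.
#' @export
negativePairScan <- function(lncScaled, geneScaled, rThreshold = -0.8) {
  lncScaled <- as.matrix(lncScaled); geneScaled <- as.matrix(geneScaled)
  if (ncol(lncScaled) != ncol(geneScaled))
    stop("profiles disagree on condition count")
  r <- stats::cor(t(lncScaled), t(geneScaled))
  idx <- which(r <= rThreshold, arr.ind = TRUE)
  out <- data.frame(lncrna_id = rownames(r)[idx[, 1L]],
                    gene_id = colnames(r)[idx[, 2L]],
                    r = r[idx], stringsAsFactors = FALSE)
  out <- out[order(out$r, out$lncrna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## moment-matching estimate of the scaled-inverse-chi-square variance prior:
## marginally s2/s0^2 ~ F(d, d0); match mean and variance of observed s2
.ebPrior <- function(s2, d) {
  m <- mean(s2)
  v <- stats::var(s2)
  if (m <= 0 || !is.finite(v) || v <= 0) return(list(d0 = Inf, s02 = max(m, 1e-12)))
  cc <- v / m^2
  denom <- cc * d - 2
  if (denom <= 0) return(list(d0 = Inf, s02 = m))
  d0 <- (2 * d - 4 + 4 * cc * d) / denom
  if (d0 <= 4) d0 <- 4.001  # variance of F undefined below; clamp
  list(d0 = d0, s02 = m * (d0 - 2) / d0)
}

#' Differentially expressed lncRNAs between two groups
#'
#' On log2(TPM + 1): logFC is the difference of group means (group2 minus
#' group1), tested with a moderated t-statistic whose per-row variance is
#' shrunk toward an empirical-Bayes prior (prior degrees of freedom d0 and
#' scale s0^2 estimated by moment matching of the residual-variance
#' distribution against its scaled-F marginal). P-values use d0 + d residual
#' degrees of freedom; BH adjustment across rows. Called iff logFC > 2 AND
#' adjusted p < 0.001, both strict.
#'
#' @param mat TPM matrix, rows = lncRNAs, columns = samples.
#' @param groups factor/character of length ncol(mat) with exactly two
#'   levels, each with >= 2 samples. logFC is level2 - level1.
#' @param logfcMin,alpha call thresholds (defaults 2 and 0.001, strict).
#' @return data.frame \code{lncrna_id}, \code{logFC}, \code{t_mod}, \code{p},
#'   \code{adj_p}, \code{called}.
#' @export
deLncrna <- function(mat, groups, logfcMin = 2, alpha = 0.001) {
  mat <- as.matrix(mat)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  n1 <- sum(groups == levels(groups)[1L])
  n2 <- sum(groups == levels(groups)[2L])
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  lm2 <- log2(mat + 1)
  g1 <- lm2[, groups == levels(groups)[1L], drop = FALSE]
  g2 <- lm2[, groups == levels(groups)[2L], drop = FALSE]
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- apply(g1, 1L, stats::var)
  v2 <- apply(g2, 1L, stats::var)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  prior <- .ebPrior(s2, d)
  s2post <- if (is.finite(prior$d0))
    (prior$d0 * prior$s02 + d * s2) / (prior$d0 + d)
  else rep(prior$s02, length(s2))
  dfTotal <- min(prior$d0 + d, 1e6)
  logFC <- m2 - m1
  tmod <- logFC / sqrt(s2post * (1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tmod), df = dfTotal)
  adj <- stats::p.adjust(p, method = "BH")
  data.frame(lncrna_id = rownames(mat), logFC = logFC, t_mod = tmod,
             p = p, adj_p = adj,
             called = logFC > logfcMin & adj < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}
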