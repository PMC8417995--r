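#' Default thresholds of the identification filters
#'
#' Organelle overlap 0.75 and known-ncRNA overlap 0.3 (removal on strictly
#' greater ratios); similarity filter e-value < 1e-4 AND alignment length >=
#' 40 aa AND percent identity >= 35 (all three jointly); minimum transcript
#' length 150 bp (strictly shorter removed); domain e-value < 1e-4; retained
#' class codes j, u, x, o.
#'
#' @return named list of thresholds.
#' @export
filterThresholds <- function() {
  list(organelle_overlap = 0.75, ncrna_overlap = 0.3,
       sim_evalue = 1e-4, sim_alen = 40, sim_pid = 35,
       min_length = 150, domain_evalue = 1e-4,
       retained_codes = c("j", "u", "x", "o"))
}

## --- class-code assignment ------------------------------------------------

.txGeom <- function(exons) {
  s <- BiocGenerics::start(exons); e <- BiocGenerics::end(exons)
  o <- order(s)
  s <- s[o]; e <- e[o]
  n <- length(s)
  list(chrom = as.character(GenomicRanges::seqnames(exons))[1L],
       strand = as.character(BiocGenerics::strand(exons))[1L],
       starts = s, ends = e, n = n,
       ## introns as 1-based closed intervals between consecutive exons
       intronStarts = if (n > 1L) e[-n] + 1L else integer(0),
       intronEnds = if (n > 1L) s[-1L] - 1L else integer(0))
}

.exonOverlapBp <- function(g1, g2) {
  ov <- 0
  for (i in seq_along(g1$starts)) {
    lo <- pmax(g1$starts[i], g2$starts)
    hi <- pmin(g1$ends[i], g2$ends)
    w <- hi - lo + 1L
    ov <- ov + sum(w[w > 0L])
  }
  ov
}

.sharedJunction <- function(q, r) {
  if (q$n < 2L || r$n < 2L) return(FALSE)
  any(paste(q$intronStarts, q$intronEnds) %in%
        paste(r$intronStarts, r$intronEnds))
}

.identicalChain <- function(q, r) {
  q$n == r$n && q$n >= 2L &&
    identical(q$intronStarts, r$intronStarts) &&
    identical(q$intronEnds, r$intronEnds)
}

.codeAgainstRef <- function(q, refGeoms) {
  qLen <- sum(q$ends - q$starts + 1L)
  sawJ <- sawI <- sawX <- sawO <- FALSE
  for (r in refGeoms) {
    if (r$chrom != q$chrom) next
    same <- r$strand == q$strand
    ov <- .exonOverlapBp(q, r)
    if (same) {
      if (.identicalChain(q, r)) return("=")
      if (q$n == 1L && r$n == 1L && ov > 0L) {
        rLen <- r$ends[1L] - r$starts[1L] + 1L
        if (ov / qLen >= 0.95 && ov / rLen >= 0.95) return("=")
      }
      if (.sharedJunction(q, r)) sawJ <- TRUE
      if (r$n >= 2L &&
          any(r$intronStarts <= q$starts[1L] & q$ends[q$n] <= r$intronEnds))
        sawI <- TRUE
      if (ov > 0L) sawO <- TRUE
    } else if (ov > 0L) sawX <- TRUE
  }
  if (sawJ) "j" else if (sawI) "i" else if (sawX) "x" else if (sawO) "o"
  else "u"
}

#' Assign a cuffcompare-style class code to one assembled transcript
#'
#' Compares a query transcript to a reference annotation and returns one of
#' \code{"="} (identical intron chain; mono-exonic: reciprocal exonic overlap
#' >= 0.95 on the same strand), \code{"j"} (shares at least one splice
#' junction with a same-strand reference transcript without being
#' \code{"="}), \code{"i"} (all exons inside a single intron of a same-strand
#' reference transcript), \code{"x"} (exonic overlap on the opposite strand),
#' \code{"o"} (same-strand exonic overlap without shared junctions) or
#' \code{"u"} (no exonic overlap, not intronic). Precedence:
#' \code{= > j > i > x > o > u}.
#'
#' @param query a \code{TranscriptSet} of length 1, or exon \code{GRanges}.
#' @param reference a \code{TranscriptSet} (the genome annotation).
#' @return single character class code.
#' @seealso \code{\link{classCodes}} for the vectorized form.
#' @export
assignClassCode <- function(query, reference) {
  if (is(query, "TranscriptSet")) {
    stopifnot(length(query) == 1L)
    query <- query@exons[[1L]]
  }
  qg <- .txGeom(query)
  refChroms <- unique(c(as.character(GenomeInfoDb::seqlevels(reference@exons)),
                        names(GenomeInfoDb::seqlengths(reference@exons))))
  if (!qg$chrom %in% refChroms)
    stop("query contig '", qg$chrom, "' absent from reference contig list")
  refGeoms <- lapply(reference@exons, .txGeom)
  .codeAgainstRef(qg, refGeoms)
}

#' Class codes for every transcript in a set
#'
#' @param queries a \code{TranscriptSet}.
#' @param reference a \code{TranscriptSet}.
#' @return named character vector of class codes.
#' @export
classCodes <- function(queries, reference) {
  refChroms <- unique(c(as.character(GenomeInfoDb::seqlevels(reference@exons)),
                        names(GenomeInfoDb::seqlengths(reference@exons))))
  refGeoms <- lapply(reference@exons, .txGeom)
  refSpans <- transcriptSpan(reference)
  qSpans <- transcriptSpan(queries)
  hits <- GenomicRanges::findOverlaps(qSpans, refSpans, ignore.strand = TRUE)
  byQ <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  out <- character(length(queries))
  names(out) <- transcriptIds(queries)
  for (i in seq_along(out)) {
    qg <- .txGeom(queries@exons[[i]])
    if (!qg$chrom %in% refChroms)
      stop("query contig '", qg$chrom, "' absent from reference contig list")
    cand <- byQ[[as.character(i)]]
    out[i] <- .codeAgainstRef(qg, refGeoms[cand])
  }
  out
}

## --- overlap filters ------------------------------------------------------

#' Fraction of a transcript's exonic length covered by an interval set
#'
#' Strand-agnostic: (exonic bp intersecting \code{intervals}) / exonic length.
#'
#' @param query \code{TranscriptSet} of length 1, or exon \code{GRanges}.
#' @param intervals \code{GRanges} interval set (e.g. organelle regions).
#' @return fraction in [0, 1]; 0 when there is no overlap.
#' @export
overlapRatio <- function(query, intervals) {
  if (is(query, "TranscriptSet")) {
    stopifnot(length(query) == 1L)
    query <- query@exons[[1L]]
  }
  if (length(intervals) == 0L) return(0)
  ints <- GenomicRanges::reduce(intervals, ignore.strand = TRUE)
  ov <- GenomicRanges::intersect(GenomicRanges::granges(query), ints,
                                 ignore.strand = TRUE)
  sum(BiocGenerics::width(ov)) / sum(BiocGenerics::width(query))
}

.overlapRatios <- function(ts, intervals) {
  out <- stats::setNames(numeric(length(ts)), transcriptIds(ts))
  if (length(intervals) == 0L || length(ts) == 0L) return(out)
  ex <- ts@exons
  nEx <- S4Vectors::elementNROWS(ex)
  flat <- unlist(ex, use.names = FALSE)
  txOf <- rep(seq_along(ex), nEx)
  ints <- GenomicRanges::reduce(intervals, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(flat, ints, ignore.strand = TRUE)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ovw <- pmin(BiocGenerics::end(flat)[qh], BiocGenerics::end(ints)[sh]) -
      pmax(BiocGenerics::start(flat)[qh], BiocGenerics::start(ints)[sh]) + 1L
    bp <- tapply(ovw, txOf[qh], sum)
    out[as.integer(names(bp))] <- as.numeric(bp)
    out <- out / as.numeric(sum(BiocGenerics::width(ex)))
  }
  out
}

#' Remove organelle and known-ncRNA contaminated transcripts
#'
#' A transcript is removed when its exonic overlap ratio with organelle
#' (chloroplast/mitochondria) intervals is strictly greater than 0.75, or —
#' if it survives that — strictly greater than 0.3 with known ncRNAs.
#'
#' @param ts a \code{TranscriptSet}.
#' @param organelle,ncrna \code{GRanges} interval sets (may be empty).
#' @param thresholds see \code{\link{filterThresholds}}.
#' @return list with \code{kept} (a \code{TranscriptSet}, subset of input)
#'   and \code{log} (data.frame \code{transcript_id}, \code{filter},
#'   \code{ratio} for removed transcripts).
#' @export
organelleNcrnaFilter <- function(ts, organelle, ncrna,
                                 thresholds = filterThresholds()) {
  orgR <- .overlapRatios(ts, organelle)
  ncR <- .overlapRatios(ts, ncrna)
  rmOrg <- orgR > thresholds$organelle_overlap
  rmNc <- !rmOrg & ncR > thresholds$ncrna_overlap
  log <- data.frame(
    transcript_id = c(names(orgR)[rmOrg], names(ncR)[rmNc]),
    filter = c(rep("organelle", sum(rmOrg)), rep("ncrna", sum(rmNc))),
    ratio = c(orgR[rmOrg], ncR[rmNc]),
    stringsAsFactors = FALSE, row.names = NULL)
  list(kept = ts[!(rmOrg | rmNc)], log = log)
}

## --- merging --------------------------------------------------------------

#' Merge per-sample transcripts into representative models
#'
#' Transcripts with identical intron chains (mono-exonic: same-strand
#' reciprocal exonic overlap >= 0.95) collapse to one representative — the
#' longest member, ties broken by lexicographically smallest id. Recurrence is
#' the number of distinct contributing samples. Loci are connected components
#' of same-strand exonic overlap among representatives.
#'
#' @param ts a \code{TranscriptSet} whose \code{source_sample} records
#'   per-sample provenance.
#' @return list with \code{merged} (a \code{TranscriptSet} whose txData gains
#'   \code{recurrence}, \code{n_members} and \code{locus}) and \code{members}
#'   (named list: representative id -> member ids).
#' @export
mergeTranscripts <- function(ts) {
  n <- length(ts)
  if (n == 0L) stop("empty transcript set")
  ex <- ts@exons
  nEx <- S4Vectors::elementNROWS(ex)
  flat <- unlist(ex, use.names = FALSE)
  txOf <- rep(seq_len(n), nEx)
  firstIdx <- cumsum(nEx) - nEx + 1L
  chrom <- as.character(GenomicRanges::seqnames(flat))[firstIdx]
  strnd <- as.character(BiocGenerics::strand(flat))[firstIdx]
  stl <- split(BiocGenerics::start(flat), txOf)
  enl <- split(BiocGenerics::end(flat), txOf)
  multi <- nEx > 1L
  key <- character(n)
  key[multi] <- vapply(which(multi), function(i) {
    s <- stl[[i]]; e <- enl[[i]]; m <- length(s)
    paste(chrom[i], strnd[i],
          paste(e[-m] + 1L, s[-1L] - 1L, collapse = ","), sep = "|")
  }, character(1))
  ## mono-exonic: union-find over same-strand reciprocal >= 0.95 overlaps
  parent <- .ufNew(n)
  monoIdx <- which(!multi)
  if (length(monoIdx) > 1L) {
    monoGr <- GenomicRanges::granges(flat[firstIdx[monoIdx]])
    hits <- GenomicRanges::findOverlaps(monoGr, monoGr, ignore.strand = FALSE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    keep <- qh < sh
    qh <- qh[keep]; sh <- sh[keep]
    if (length(qh)) {
      w1 <- BiocGenerics::width(monoGr)[qh]
      w2 <- BiocGenerics::width(monoGr)[sh]
      ov <- BiocGenerics::width(IRanges::pintersect(
        IRanges::ranges(monoGr)[qh], IRanges::ranges(monoGr)[sh]))
      recip <- ov / w1 >= 0.95 & ov / w2 >= 0.95
      for (k in which(recip))
        parent <- .ufUnion(parent, monoIdx[qh[k]], monoIdx[sh[k]])
    }
  }
  ## multi-exonic: same key -> same group
  if (any(multi)) {
    byKey <- split(which(multi), key[multi])
    for (grp in byKey) if (length(grp) > 1L)
      for (k in grp[-1L]) parent <- .ufUnion(parent, grp[1L], k)
  }
  comp <- .ufComponents(parent)
  ids <- transcriptIds(ts)
  lens <- exonicLength(ts)
  samples <- ts@txData$source_sample
  groups <- split(seq_len(n), comp)
  repIdx <- vapply(groups, function(g) {
    g[order(-lens[g], ids[g])][1L]
  }, integer(1))
  recurrence <- vapply(groups, function(g) {
    s <- unique(samples[g][nzchar(samples[g])])
    max(1L, length(s))
  }, integer(1))
  nMembers <- lengths(groups)
  merged <- ts[repIdx]
  merged@txData$recurrence <- unname(recurrence)
  merged@txData$n_members <- unname(nMembers)
  ## loci: components of same-strand exonic overlap among representatives
  m <- length(merged)
  lp <- .ufNew(m)
  hits <- GenomicRanges::findOverlaps(merged@exons, merged@exons,
                                      ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  for (k in which(qh < sh)) lp <- .ufUnion(lp, qh[k], sh[k])
  merged@txData$locus <- sprintf("LOC%05d", .ufComponents(lp))
  members <- lapply(groups, function(g) ids[g])
  names(members) <- ids[repIdx]
  list(merged = merged, members = members)
}

## --- assembly features and the ML contamination filter --------------------

#' Assembly features of merged transcripts
#'
#' The five features of the contamination classifier: recurrence ratio
#' (recurrence / number of samples in the expression matrix), max TPM, mean
#' TPM, exonic length (bp) and exon count.
#'
#' @param merged a merged \code{TranscriptSet} (txData has \code{recurrence}).
#' @param expr expression container (see \code{\link{ExpressionMatrix}}) with
#'   one row per merged transcript.
#' @return numeric matrix, rows = transcripts, columns = the five features.
#' @export
extractFeatures <- function(merged, expr) {
  m <- tpm(expr)
  ids <- transcriptIds(merged)
  miss <- setdiff(ids, rownames(m))
  if (length(miss))
    stop("transcript(s) missing from expression matrix: ",
         paste(miss, collapse = ", "))
  rec <- merged@txData$recurrence
  if (is.null(rec)) stop("merged set lacks recurrence; run mergeTranscripts")
  sub <- m[ids, , drop = FALSE]
  cbind(recurrence_ratio = rec / ncol(m),
        max_tpm = apply(sub, 1L, max),
        mean_tpm = rowMeans(sub),
        length = unname(exonicLength(merged)),
        exon_count = unname(exonCount(merged)))
}

## hand-rolled CART + bagging (no randomForest in the stack); gini splits,
## feature subsampling per node
.bestSplit <- function(x, y, minNode) {
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  n <- length(ys)
  cum1 <- cumsum(ys)
  tot1 <- cum1[n]
  i <- seq_len(n - 1L)
  valid <- xs[i] < xs[i + 1L] & i >= minNode & (n - i) >= minNode
  if (!any(valid)) return(NULL)
  nl <- i; nr <- n - i
  p1l <- cum1[i] / nl; p1r <- (tot1 - cum1[i]) / nr
  gini <- nl * 2 * p1l * (1 - p1l) + nr * 2 * p1r * (1 - p1r)
  gini[!valid] <- Inf
  k <- which.min(gini)
  list(threshold = (xs[k] + xs[k + 1L]) / 2, score = gini[k])
}

.treeFit <- function(X, y, mtry, maxDepth, minNode, depth = 0L) {
  n <- length(y)
  p1 <- mean(y)
  if (depth >= maxDepth || n < 2L * minNode || p1 == 0 || p1 == 1)
    return(list(leaf = TRUE, p = p1))
  feats <- sample.int(ncol(X), mtry)
  best <- NULL
  for (f in feats) {
    sp <- .bestSplit(X[, f], y, minNode)
    if (!is.null(sp) && (is.null(best) || sp$score < best$score)) {
      best <- sp; best$feature <- f
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, p = p1))
  left <- X[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = .treeFit(X[left, , drop = FALSE], y[left], mtry, maxDepth,
                       minNode, depth + 1L),
       right = .treeFit(X[!left, , drop = FALSE], y[!left], mtry, maxDepth,
                        minNode, depth + 1L))
}

.treePredictOne <- function(tree, x) {
  while (!tree$leaf)
    tree <- if (x[tree$feature] <= tree$threshold) tree$left else tree$right
  tree$p
}

.forestFit <- function(X, y, nTrees = 100L, mtry = 2L, maxDepth = 6L,
                       minNode = 3L) {
  lapply(seq_len(nTrees), function(b) {
    idx <- sample.int(nrow(X), replace = TRUE)
    .treeFit(X[idx, , drop = FALSE], y[idx], mtry, maxDepth, minNode)
  })
}

.forestPredict <- function(forest, X) {
  votes <- vapply(forest, function(tr)
    apply(X, 1L, function(x) .treePredictOne(tr, x)), numeric(nrow(X)))
  if (nrow(X) == 1L) votes <- matrix(votes, nrow = 1L)
  rowMeans(votes) > 0.5
}

.marginFit <- function(X, y) {
  fit <- glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                        alpha = 0, lambda = 0.01, standardize = TRUE)
  list(fit = fit)
}

.marginPredict <- function(margin, X) {
  as.vector(stats::predict(margin$fit, newx = X, type = "class")) == "1"
}

#' Train the two-classifier contamination filter
#'
#' Fits a forest-style classifier (bagged decision trees) and a margin-style
#' classifier (L2-regularized logistic separator) to distinguish
#' reference-identical ("=", \code{equal_like}) from intronic ("i",
#' \code{intronic_like}) transcripts on their five assembly features. A 20\%
#' stratified hold-out accuracy (under the combination rule) is recorded,
#' after which both classifiers are refitted on all examples. Deterministic
#' for a fixed seed.
#'
#' @param eqFeatures,intronFeatures numeric feature matrices (rows =
#'   transcripts) for the two training classes; at least 20 rows each.
#' @param rule combination rule: \code{"both_agree"} (default: predict
#'   intronic only on consensus), \code{"either"}, \code{"forest_only"},
#'   \code{"margin_only"}.
#' @param seed integer seed.
#' @return a fitted \linkS4class{ContaminationModel}.
#' @export
trainContaminationFilter <- function(eqFeatures, intronFeatures,
                                     rule = c("both_agree", "either",
                                              "forest_only", "margin_only"),
                                     seed = 1L) {
  rule <- match.arg(rule)
  Xe <- as.matrix(eqFeatures); Xi <- as.matrix(intronFeatures)
  if (nrow(Xe) == 0L || nrow(Xi) == 0L) stop("a training class is empty")
  if (nrow(Xe) < 20L || nrow(Xi) < 20L)
    stop("need >= 20 examples per class (got ", nrow(Xe), " '=' and ",
         nrow(Xi), " 'i')")
  ratio <- max(nrow(Xe), nrow(Xi)) / min(nrow(Xe), nrow(Xi))
  if (ratio > 50) warning("class imbalance exceeds 50:1")
  X <- rbind(Xe, Xi)
  y <- c(rep(0L, nrow(Xe)), rep(1L, nrow(Xi)))  # 1 = intronic_like
  set.seed(seed)
  hold <- c(sample(which(y == 0L), max(1L, round(0.2 * nrow(Xe)))),
            sample(which(y == 1L), max(1L, round(0.2 * nrow(Xi)))))
  trIdx <- setdiff(seq_along(y), hold)
  forest <- .forestFit(X[trIdx, , drop = FALSE], y[trIdx])
  margin <- .marginFit(X[trIdx, , drop = FALSE], y[trIdx])
  predHold <- .combineRule(.forestPredict(forest, X[hold, , drop = FALSE]),
                           .marginPredict(margin, X[hold, , drop = FALSE]),
                           rule)
  acc <- mean(predHold == (y[hold] == 1L))
  ## refit on everything for deployment
  forest <- .forestFit(X, y)
  margin <- .marginFit(X, y)
  new("ContaminationModel", forest = forest, margin = margin, rule = rule,
      featureNames = colnames(X),
      trainSummary = list(n_equal = nrow(Xe), n_intronic = nrow(Xi),
                          heldout_accuracy = acc),
      fitted = TRUE)
}

.combineRule <- function(forestIntronic, marginIntronic, rule) {
  switch(rule,
         both_agree = forestIntronic & marginIntronic,
         either = forestIntronic | marginIntronic,
         forest_only = forestIntronic,
         margin_only = marginIntronic)
}

#' Predict contamination class for candidate transcripts
#'
#' @param model a fitted \linkS4class{ContaminationModel}.
#' @param features numeric feature matrix with row names = transcript ids.
#' @return data.frame with per-classifier predictions and the combined
#'   \code{prediction} (\code{equal_like}/\code{intronic_like}).
#' @export
predictContamination <- function(model, features) {
  if (!model@fitted) stop("model is not fitted")
  X <- as.matrix(features)
  if (!identical(colnames(X), model@featureNames))
    X <- X[, model@featureNames, drop = FALSE]
  if (is.null(rownames(X))) rownames(X) <- sprintf("tx%d", seq_len(nrow(X)))
  fi <- .forestPredict(model@forest, X)
  mi <- .marginPredict(model@margin, X)
  comb <- .combineRule(fi, mi, model@rule)
  data.frame(transcript_id = rownames(X),
             forest = ifelse(fi, "intronic_like", "equal_like"),
             margin = ifelse(mi, "intronic_like", "equal_like"),
             prediction = ifelse(comb, "intronic_like", "equal_like"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply the contamination filter to candidate transcripts
#'
#' Under the default \code{both_agree} rule a candidate is removed iff both
#' classifiers predict \code{intronic_like}; kept and removed ids partition
#' the input.
#'
#' @inheritParams predictContamination
#' @return list with \code{kept} and \code{removed} id vectors and the
#'   per-candidate \code{predictions} data.frame.
#' @export
applyContaminationFilter <- function(model, features) {
  pred <- predictContamination(model, features)
  removed <- pred$transcript_id[pred$prediction == "intronic_like"]
  list(kept = setdiff(pred$transcript_id, removed), removed = removed,
       predictions = pred)
}

## --- coding-potential stand-in (ORF + Fickett TESTCODE) -------------------

## Fickett (1982) TESTCODE lookup tables, position and composition parameters
.fickettPosProb <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
.fickettPosWeight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
.fickettPosCut <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)
.fickettCompProb <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
.fickettCompWeight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
.fickettCompCut <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0)

.fickettScore <- function(chars) {
  acgt <- chars[chars != "N"]
  if (!length(acgt)) return(0)
  score <- 0
  pos <- (seq_along(chars) - 1L) %% 3L  # frame position of each base
  for (b in c("A", "C", "G", "T")) {
    cnt <- vapply(0:2, function(k) sum(chars[pos == k] == b), numeric(1))
    posPar <- max(cnt) / (min(cnt) + 1)
    idx <- which(posPar >= .fickettPosCut)[1L]
    score <- score + .fickettPosProb[[b]][idx] * .fickettPosWeight[[b]]
    compPar <- sum(acgt == b) / length(acgt)
    idx <- which(compPar >= .fickettCompCut)[1L]
    score <- score + .fickettCompProb[[b]][idx] * .fickettCompWeight[[b]]
  }
  score
}

.longestOrf <- function(chars) {
  n <- length(chars)
  best <- 0L
  for (frame in 0:2) {
    nCodon <- (n - frame) %/% 3L
    if (nCodon < 2L) next
    idx <- frame + 3L * (seq_len(nCodon) - 1L) + 1L
    codons <- paste0(chars[idx], chars[idx + 1L], chars[idx + 2L])
    starts <- which(codons == "ATG")
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    for (s in starts) {
      nxt <- stops[stops > s]
      if (length(nxt)) best <- max(best, nxt[1L] - s)
    }
  }
  best
}

#' Score the coding potential of a nucleotide sequence
#'
#' A transparent stand-in for trained coding-potential classifiers: the
#' longest open reading frame on the three forward frames (ATG to stop;
#' peptide length counted in amino acids including the initiator Met) plus
#' the Fickett TESTCODE statistic from the published position/composition
#' lookup tables. Default verdict: \code{coding} iff the longest ORF is
#' >= 100 aa, or the Fickett score is >= 0.95 with an ORF >= 50 aa.
#'
#' @param sequence character string or \code{DNAString} over A/C/G/T/N.
#' @return list with \code{longest_orf_aa}, \code{orf_coverage},
#'   \code{fickett_score} and \code{verdict} ("coding"/"noncoding").
#' @export
scoreCodingPotential <- function(sequence) {
  s <- toupper(as.character(sequence))
  if (nchar(s) < 1L) stop("empty sequence")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c("A", "C", "G", "T", "N")))
    stop("sequence contains characters outside A/C/G/T/N")
  orf <- .longestOrf(chars)
  fick <- .fickettScore(chars)
  list(longest_orf_aa = orf,
       orf_coverage = 3 * orf / length(chars),
       fickett_score = fick,
       verdict = if (orf >= 100L || (fick >= 0.95 && orf >= 50L))
         "coding" else "noncoding")
}

## --- coding-ability cascade -----------------------------------------------

#' Remove coding-capable transcripts
#'
#' Applies, in order: the similarity filter (removed when any protein hit has
#' e-value < 1e-4 AND alignment length >= 40 aa AND percent identity >= 35,
#' all jointly), the length filter (removed when sequence length < 150 bp,
#' strictly), the coding-potential filter
#' (\code{\link{scoreCodingPotential}}, or an externally supplied verdict
#' table), and the domain filter (removed when any domain hit has e-value <
#' 1e-4). The survivors are the lncRNA set.
#'
#' @param ids transcript ids entering the cascade.
#' @param sequences named \code{DNAStringSet} (or character vector) holding
#'   every transcript's sequence.
#' @param simHits protein-similarity hit table (see
#'   \code{\link{readHitTable}}); may have zero rows.
#' @param domainHits precomputed domain hit table, same layout.
#' @param thresholds see \code{\link{filterThresholds}}.
#' @param codingVerdicts optional named character vector
#'   ("coding"/"noncoding") overriding the built-in scorer (adapter for
#'   external classifiers).
#' @return list with \code{lncrna} (surviving ids), \code{log} (per-stage
#'   survivor counts) and \code{removals} (data.frame id, stage).
#' @export
codingAbilityCascade <- function(ids, sequences, simHits = NULL,
                                 domainHits = NULL,
                                 thresholds = filterThresholds(),
                                 codingVerdicts = NULL) {
  seqNames <- names(sequences)
  miss <- setdiff(ids, seqNames)
  if (length(miss))
    stop("transcript(s) missing from FASTA: ", paste(miss, collapse = ", "))
  lens <- stats::setNames(
    if (methods::is(sequences, "XStringSet"))
      BiocGenerics::width(sequences) else nchar(sequences), seqNames)
  removals <- data.frame(transcript_id = character(0), stage = character(0),
                         stringsAsFactors = FALSE)
  log <- data.frame(stage = character(0), n_in = integer(0),
                    n_removed = integer(0), n_out = integer(0))
  cur <- ids
  stage <- function(name, removedIds) {
    removedIds <- intersect(cur, removedIds)
    log <<- rbind(log, data.frame(stage = name, n_in = length(cur),
                                  n_removed = length(removedIds),
                                  n_out = length(cur) - length(removedIds)))
    if (length(removedIds))
      removals <<- rbind(removals,
                         data.frame(transcript_id = removedIds, stage = name,
                                    stringsAsFactors = FALSE))
    cur <<- setdiff(cur, removedIds)
  }
  simRm <- character(0)
  if (!is.null(simHits) && nrow(simHits)) {
    hit <- simHits$e_value < thresholds$sim_evalue &
      simHits$alignment_length >= thresholds$sim_alen &
      simHits$percent_identity >= thresholds$sim_pid
    simRm <- unique(simHits$query_id[hit])
  }
  stage("similarity", simRm)
  stage("length", cur[lens[cur] < thresholds$min_length])
  codingRm <- if (!is.null(codingVerdicts)) {
    names(codingVerdicts)[codingVerdicts == "coding"]
  } else {
    cur[vapply(cur, function(id)
      scoreCodingPotential(as.character(sequences[[id]]))$verdict == "coding",
      logical(1))]
  }
  stage("coding_potential", codingRm)
  domRm <- character(0)
  if (!is.null(domainHits) && nrow(domainHits))
    domRm <- unique(domainHits$query_id[domainHits$e_value <
                                          thresholds$domain_evalue])
  stage("domain", domRm)
  list(lncrna = cur, log = log, removals = removals)
}
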