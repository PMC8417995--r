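#' Simulate a genome with a reference gene annotation
#'
#' Uniform-random contig sequences with non-overlapping genes of 1-8 exons on
#' both strands, placed with generous intergenic gaps (room for intergenic
#' transcripts and promoters). Two organelle contigs (\code{chrC},
#' \code{chrM}) are added, each with a designated organelle interval covering
#' part of the contig, mirroring real chloroplast/mitochondrial filtering.
#' Pure function of its arguments: a fixed seed gives byte-identical output.
#'
#' @param nContigs number of nuclear contigs (default 2).
#' @param contigLen length of each nuclear contig in bp (default 200000).
#' @param nGenes total genes to place (default 60).
#' @param seed integer seed.
#' @param organelle add chrC/chrM contigs (default TRUE).
#' @return list with \code{genome} (\code{DNAStringSet}), \code{annotation}
#'   (a \code{TranscriptSet} with contig lengths set) and \code{organelleBed}
#'   (\code{GRanges}).
#' @export
makeGenome <- function(nContigs = 2L, contigLen = 900000L, nGenes = 200L,
                       seed = 1L, organelle = TRUE) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  contigs <- paste0("chr", seq_len(nContigs))
  seqs <- lapply(contigs, function(cc)
    paste(sample(bases, contigLen, replace = TRUE), collapse = ""))
  names(seqs) <- contigs
  perContig <- rep(nGenes %/% nContigs, nContigs)
  if (nGenes %% nContigs) perContig[seq_len(nGenes %% nContigs)] <-
    perContig[seq_len(nGenes %% nContigs)] + 1L
  exonsList <- list()
  geneIds <- character(0)
  gi <- 0L
  for (ci in seq_len(nContigs)) {
    cursor <- 1L
    for (g in seq_len(perContig[ci])) {
      gi <- gi + 1L
      gap <- sample(2000:4000, 1L)
      nEx <- sample(1:8, 1L)
      widths <- sample(100:400, nEx, replace = TRUE)
      introns <- if (nEx > 1L) sample(300:800, nEx - 1L, replace = TRUE)
                 else integer(0)
      span <- sum(widths) + sum(introns)
      startPos <- cursor + gap
      if (startPos + span - 1L > contigLen)
        stop("gene density infeasible: reduce nGenes or increase contigLen")
      starts <- startPos + cumsum(c(0L, widths[-nEx] + introns))
      ends <- starts + widths - 1L
      strand <- sample(c("+", "-"), 1L)
      id <- sprintf("G%04d", gi)
      exonsList[[paste0(id, ".t1")]] <- GenomicRanges::GRanges(
        contigs[ci], IRanges::IRanges(starts, ends), strand = strand)
      geneIds <- c(geneIds, id)
      cursor <- startPos + span - 1L
    }
  }
  allContigs <- contigs
  seqlens <- stats::setNames(rep(contigLen, nContigs), contigs)
  organelleBed <- GenomicRanges::GRanges()
  if (organelle) {
    for (oc in c("chrC", "chrM"))
      seqs[[oc]] <- paste(sample(bases, 20000L, replace = TRUE),
                          collapse = "")
    allContigs <- c(contigs, "chrC", "chrM")
    seqlens <- c(seqlens, chrC = 20000L, chrM = 20000L)
    organelleBed <- GenomicRanges::GRanges(
      c("chrC", "chrM"), IRanges::IRanges(c(1L, 1L), c(12000L, 12000L)))
  }
  exl <- GenomicRanges::GRangesList(exonsList)
  GenomeInfoDb::seqlevels(exl) <- allContigs
  GenomeInfoDb::seqlengths(exl) <- seqlens
  annotation <- new("TranscriptSet", exons = exl,
                    txData = S4Vectors::DataFrame(
                      transcript_id = names(exl), gene_id = geneIds,
                      source_sample = rep("", length(exl)),
                      row.names = names(exl)))
  methods::validObject(annotation)
  list(genome = Biostrings::DNAStringSet(unlist(seqs)),
       annotation = annotation, organelleBed = organelleBed)
}

## free intergenic blocks on nuclear contigs, away from genes
.freeBlocks <- function(annotation, margin = 500L, blockLen = 1400L) {
  spans <- geneSpans(annotation)
  blocks <- list()
  for (cc in unique(as.character(GenomicRanges::seqnames(spans)))) {
    cs <- spans[as.character(GenomicRanges::seqnames(spans)) == cc]
    cs <- BiocGenerics::sort(cs, ignore.strand = TRUE)
    clen <- GenomeInfoDb::seqlengths(spans)[cc]
    bounds <- c(1L, BiocGenerics::end(cs) + margin)
    uppers <- c(BiocGenerics::start(cs) - margin, clen)
    for (k in seq_along(bounds)) {
      lo <- bounds[k]; hi <- uppers[k]
      while (hi - lo + 1L >= blockLen) {
        blocks[[length(blocks) + 1L]] <- c(cc = cc, lo = lo,
                                           hi = lo + blockLen - 1L)
        lo <- lo + blockLen
      }
    }
  }
  blocks
}

#' Simulate a per-sample transcript assembly with planted class codes
#'
#' For each planted class code the transcript's geometry realizes that code's
#' definition against the reference: identical intron chains for \code{"="},
#' a shared-but-not-identical junction set for \code{"j"}, placement strictly
#' inside a reference intron for \code{"i"}, opposite-strand exon overlap for
#' \code{"x"}, same-strand exon overlap without shared junctions for
#' \code{"o"}, and reserved intergenic blocks for \code{"u"}. Contaminants
#' are planted with controlled overlap ratios straddling the 0.75 organelle
#' and 0.3 known-ncRNA thresholds, as transcripts carrying protein
#' similarity / domain hits (coding), and as intronic-artifact transcripts
#' whose assembly features mimic the "i" class. Each underlying transcript is
#' emitted once per contributing sample (\code{<id>_s<k>}), so merging
#' recovers the planted recurrence.
#'
#' @param genomeSim output of \code{\link{makeGenome}}.
#' @param rates named fractions over the six class codes (must sum to 1).
#' @param nTranscripts planted transcripts across codes (default 200).
#' @param nSamples number of assembly samples (default 60).
#' @param contamination list: counts of \code{organelle}, \code{ncrna},
#'   \code{coding}, \code{artifact} contaminants.
#' @param seed integer seed.
#' @return list with \code{assembly} (\code{TranscriptSet} of per-sample
#'   copies), \code{ncrnaBed} (\code{GRanges}), \code{simHits} /
#'   \code{domainHits} (hit tables for the coding cascade) and \code{truth}
#'   (per-transcript class codes, categories, contaminant sets, recurrence,
#'   representative ids, expected surviving lncRNA set).
#' @export
makeAssembly <- function(genomeSim,
                         rates = c("=" = 0.25, "j" = 0.15, "i" = 0.15,
                                   "u" = 0.25, "x" = 0.10, "o" = 0.10),
                         nTranscripts = 200L, nSamples = 60L,
                         contamination = list(organelle = 8L, ncrna = 8L,
                                              coding = 10L, artifact = 15L),
                         seed = 1L) {
  stopifnot(abs(sum(rates) - 1) < 1e-9,
            all(names(rates) %in% c("=", "j", "i", "u", "x", "o")))
  set.seed(.deriveSeed(seed, 2L))
  annotation <- genomeSim$annotation
  refGeoms <- lapply(annotation@exons, .txGeom)
  nGenes <- length(refGeoms)
  blocks <- .freeBlocks(annotation)
  blockCursor <- 0L
  takeBlock <- function() {
    blockCursor <<- blockCursor + 1L
    if (blockCursor > length(blocks))
      stop("not enough intergenic room; increase contigLen or reduce counts")
    blocks[[blockCursor]]
  }
  counts <- round(rates * nTranscripts)
  planted <- list()   # per base transcript: exons GRanges, code, category
  addTx <- function(gr, code, category) {
    id <- sprintf("T%04d", length(planted) + 1L)
    planted[[id]] <<- list(exons = gr, code = code, category = category)
    id
  }
  ## each gene hosts at most one planted transcript, so distinct planted
  ## transcripts can never collapse into one merged representative
  geneAvail <- rep(TRUE, nGenes)
  pickGene <- function(pred) {
    cand <- which(geneAvail)
    cand <- cand[sample.int(length(cand))]
    for (i in cand) {
      g <- refGeoms[[i]]
      if (pred(g)) {
        geneAvail[i] <<- FALSE
        return(g)
      }
    }
    stop("no unused reference gene satisfies the requested geometry; ",
         "increase nGenes")
  }
  mkGr <- function(chrom, starts, ends, strand)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                           strand = strand,
                           seqlengths = GenomeInfoDb::seqlengths(
                             annotation@exons))
  for (code in names(counts)) for (k in seq_len(counts[[code]])) {
    if (code == "=") {
      g <- pickGene(function(g) TRUE)
      addTx(mkGr(g$chrom, g$starts, g$ends, g$strand), "=", "ref_equal")
    } else if (code == "j") {
      g <- pickGene(function(g) g$n >= 3L || (g$n == 2L &&
                      g$ends[1L] - g$starts[1L] + 1L >= 240L))
      if (g$n >= 3L) {
        n <- g$n
        starts <- g$starts[-n]; ends <- g$ends[-n]
        ext <- min(100L, g$intronEnds[n - 1L] - g$intronStarts[n - 1L] - 20L)
        ends[n - 1L] <- ends[n - 1L] + max(1L, ext)
        addTx(mkGr(g$chrom, starts, ends, g$strand), "j", "lncRNA")
      } else {
        s1 <- g$starts[1L]; e1 <- g$ends[1L]
        starts <- c(s1, s1 + 140L, g$starts[2L])
        ends <- c(s1 + 79L, e1, g$ends[2L])
        addTx(mkGr(g$chrom, starts, ends, g$strand), "j", "lncRNA")
      }
    } else if (code == "i") {
      g <- pickGene(function(g) g$n >= 2L &&
                      any(g$intronEnds - g$intronStarts + 1L >= 200L))
      ii <- which(g$intronEnds - g$intronStarts + 1L >= 200L)[1L]
      addTx(mkGr(g$chrom, g$intronStarts[ii] + 40L, g$intronEnds[ii] - 40L,
                 g$strand), "i", "intronic")
    } else if (code == "x") {
      g <- pickGene(function(g) TRUE)
      w <- min(250L, g$ends[1L] - g$starts[1L] + 200L)
      addTx(mkGr(g$chrom, g$starts[1L] + 10L, g$starts[1L] + 9L + w,
                 if (g$strand == "+") "-" else "+"), "x", "lncRNA")
    } else if (code == "o") {
      g <- pickGene(function(g) g$n >= 2L)
      s1 <- g$starts[1L]
      lo <- max(1L, s1 - 150L)
      hi <- s1 + min(150L, g$ends[1L] - s1 - 1L)
      addTx(mkGr(g$chrom, lo, hi, g$strand), "o", "lncRNA")
    } else if (code == "u") {
      b <- takeBlock()
      w <- sample(250:600, 1L)
      lo <- as.integer(b["lo"]) + sample(100:300, 1L)
      addTx(mkGr(b["cc"], lo, lo + w - 1L, sample(c("+", "-"), 1L)),
            "u", "lncRNA")
    }
  }
  ## organelle contaminants: overlap ratios straddling 0.75
  ncrnaBed <- GenomicRanges::GRanges()
  orgIds <- ncIds <- codingIds <- artifactIds <- character(0)
  nOrg <- contamination$organelle
  if (nOrg > 0L) {
    fracs <- rep(c(0.72, 0.74, 0.76, 0.80), length.out = nOrg)
    chroms <- rep(c("chrC", "chrM"), length.out = nOrg)
    for (k in seq_len(nOrg)) {
      f <- fracs[k]
      w <- 600L + 50L * k    # distinct widths keep the transcripts distinct
      start <- as.integer(12001L - f * w)   # overlap with [1,12000] = f * w
      gr <- mkGr(chroms[k], start, start + w - 1L, "+")
      id <- addTx(gr, "u", if (f > 0.75) "organelle_drop" else "organelle_keep")
      if (f > 0.75) orgIds <- c(orgIds, id)
    }
  }
  ## known-ncRNA contaminants: intervals in reserved blocks, ratios
  ## straddling 0.3
  nNc <- contamination$ncrna
  if (nNc > 0L) {
    fracs <- rep(c(0.26, 0.29, 0.31, 0.35), length.out = nNc)
    ncList <- list()
    for (k in seq_len(nNc)) {
      b <- takeBlock()
      f <- fracs[k]
      ncLo <- as.integer(b["lo"]) + 50L
      ncList[[k]] <- GenomicRanges::GRanges(
        b["cc"], IRanges::IRanges(ncLo, ncLo + 999L))
      txLo <- ncLo + as.integer((1 - f) * 1000L)
      id <- addTx(mkGr(b["cc"], txLo, txLo + 999L, "+"), "u",
                  if (f > 0.3) "ncrna_drop" else "ncrna_keep")
      if (f > 0.3) ncIds <- c(ncIds, id)
    }
    ncrnaBed <- unlist(GenomicRanges::GRangesList(ncList))
  }
  ## coding contaminants: intergenic geometry, removed via hit tables
  nCod <- contamination$coding
  if (nCod > 0L) for (k in seq_len(nCod)) {
    b <- takeBlock()
    lo <- as.integer(b["lo"]) + 100L
    id <- addTx(mkGr(b["cc"], lo, lo + 599L, "+"), "u", "coding")
    codingIds <- c(codingIds, id)
  }
  ## intronic-artifact contaminants: intergenic geometry, i-like features
  nArt <- contamination$artifact
  if (nArt > 0L) for (k in seq_len(nArt)) {
    b <- takeBlock()
    lo <- as.integer(b["lo"]) + 200L
    id <- addTx(mkGr(b["cc"], lo, lo + sample(180:280, 1L), "+"), "u",
                "artifact")
    artifactIds <- c(artifactIds, id)
  }
  ## per-sample copies with planted recurrence
  ids <- names(planted)
  category <- vapply(planted, `[[`, character(1), "category")
  code <- vapply(planted, `[[`, character(1), "code")
  recurrence <- vapply(category, function(cat) switch(cat,
    ref_equal = sample(10:25, 1L),
    intronic = sample(1:2, 1L),
    artifact = 1L,
    sample(8:20, 1L)), integer(1))
  recurrence <- pmin(recurrence, nSamples)
  exonsList <- list()
  geneIdsOut <- character(0)
  sampleOut <- character(0)
  repId <- character(length(ids)); names(repId) <- ids
  copies <- vector("list", length(ids)); names(copies) <- ids
  for (i in seq_along(ids)) {
    sIdx <- sort(sample.int(nSamples, recurrence[i]))
    cps <- sprintf("%s_s%02d", ids[i], sIdx)
    for (k in seq_along(cps)) {
      exonsList[[cps[k]]] <- planted[[ids[i]]]$exons
      geneIdsOut <- c(geneIdsOut, sprintf("XLOC_%s", ids[i]))
      sampleOut <- c(sampleOut, sprintf("s%02d", sIdx[k]))
    }
    repId[i] <- cps[1L]
    copies[[i]] <- cps
  }
  exl <- GenomicRanges::GRangesList(exonsList)
  GenomeInfoDb::seqlevels(exl) <- GenomeInfoDb::seqlevels(annotation@exons)
  GenomeInfoDb::seqlengths(exl) <-
    GenomeInfoDb::seqlengths(annotation@exons)
  assembly <- new("TranscriptSet", exons = exl,
                  txData = S4Vectors::DataFrame(
                    transcript_id = names(exl), gene_id = geneIdsOut,
                    source_sample = sampleOut, row.names = names(exl)))
  methods::validObject(assembly)
  ## hit tables keyed by representative ids (what the cascade sees)
  mkHits <- function(qids, e, alen, pid) {
    if (!length(qids)) return(NULL)
    data.frame(query_id = qids, subject_id = paste0("SP_", seq_along(qids)),
               percent_identity = pid, alignment_length = alen,
               mismatches = 0, gap_opens = 0, q_start = 1, q_end = alen * 3,
               s_start = 1, s_end = alen, e_value = e, bit_score = 500,
               stringsAsFactors = FALSE)
  }
  simCoding <- codingIds[seq_len(ceiling(length(codingIds) / 2))]
  domCoding <- setdiff(codingIds, simCoding)
  ## decoy hits that FAIL the similarity conjunction (kept transcripts)
  lncIds <- ids[category == "lncRNA"]
  decoys <- utils::head(lncIds, 6L)
  simHits <- rbind(mkHits(repId[simCoding], 1e-30, 100, 80),
                   mkHits(utils::head(repId[decoys], 3L), 1e-30, 30, 80),
                   mkHits(utils::tail(repId[decoys], 3L), 1e-30, 100, 20))
  domainHits <- mkHits(repId[domCoding], 1e-10, 150, 60)
  expectedLncrna <- ids[category %in%
                          c("lncRNA", "organelle_keep", "ncrna_keep")]
  truth <- list(
    true_class_code = code,
    category = category,
    contaminated_ids = list(organelle = orgIds, ncrna = ncIds,
                            coding = codingIds, artifact = artifactIds),
    recurrence = recurrence,
    rep_id = repId,
    copies = copies,
    expected_lncrna = expectedLncrna,
    n_samples = nSamples)
  list(assembly = assembly, ncrnaBed = ncrnaBed, simHits = simHits,
       domainHits = domainHits, truth = truth)
}

#' Simulate an expression matrix with planted structure
#'
#' Log-normal multiplicative noise on per-row baseline TPM. Planted
#' structure: tissue-specific rows are boosted \code{fold}-fold in every
#' sample of one tissue; module members share a latent per-sample profile
#' (inducing pairwise TPM correlation above 0.8 in expectation); negative
#' pairs share a latent profile with the sign flipped on the gene side;
#' everything else is independent noise. Samples carry a true tissue, but
#' only the described fraction exposes it as metadata (mirroring incomplete
#' sample descriptions in public archives).
#'
#' @param ids row ids hosting specific/module/negative-lncRNA structure
#'   (e.g. lncRNA representatives).
#' @param geneIds additional row ids hosting module/negative-gene structure
#'   (e.g. coding genes); default none.
#' @param tissues tissue names (default 20 tissues).
#' @param params list: \code{n_specific} (20), \code{n_modules} (3),
#'   \code{module_size} (7: 2 lncRNAs + 5 genes), \code{n_negative_pairs}
#'   (10), \code{noise_sd} (0.1, log2 units), \code{fold} (100),
#'   \code{module_amp} (0.5), \code{neg_amp} (0.35).
#' @param samplesPerTissue described samples per tissue (default 2).
#' @param undescribedFrac fraction of extra samples lacking a tissue
#'   description (default 1/3 of the total).
#' @param baseTpm optional named baseline TPM per row id.
#' @param seed integer seed.
#' @return list with \code{expr} (see \code{\link{ExpressionMatrix}}) and
#'   \code{truth} (\code{planted_specific}, \code{planted_modules},
#'   \code{planted_negative_pairs}, per-sample true tissues).
#' @export
makeExpression <- function(ids, geneIds = character(0),
                           tissues = paste0("tissue", sprintf("%02d", 1:20)),
                           params = list(), samplesPerTissue = 2L,
                           undescribedFrac = 1 / 3, baseTpm = NULL,
                           seed = 1L) {
  p <- utils::modifyList(list(n_specific = 20L, n_modules = 3L,
                              module_size = 7L, n_negative_pairs = 10L,
                              noise_sd = 0.1, fold = 100, module_amp = 0.5,
                              neg_amp = 0.35), params)
  set.seed(.deriveSeed(seed, 3L))
  allIds <- c(ids, geneIds)
  if (anyDuplicated(allIds)) stop("duplicate row ids")
  nDesc <- length(tissues) * samplesPerTissue
  nUndesc <- round(nDesc * undescribedFrac / (1 - undescribedFrac))
  nSamp <- nDesc + nUndesc
  sampleIds <- sprintf("s%02d", seq_len(nSamp))
  trueTissue <- c(rep(tissues, each = samplesPerTissue),
                  sample(tissues, nUndesc, replace = TRUE))
  described <- c(rep(TRUE, nDesc), rep(FALSE, nUndesc))
  ## disjoint structure assignment
  lncPool <- ids
  take <- function(pool, n, what) {
    if (length(pool) < n)
      stop("not enough ids to host planted ", what)
    pool[seq_len(n)]
  }
  specific <- take(lncPool, p$n_specific, "tissue-specific rows")
  lncPool <- setdiff(lncPool, specific)
  nModLnc <- min(2L, p$module_size - 1L)
  modLnc <- take(lncPool, p$n_modules * nModLnc, "module lncRNAs")
  lncPool <- setdiff(lncPool, modLnc)
  negLnc <- take(lncPool, p$n_negative_pairs, "negative-pair lncRNAs")
  lncPool <- setdiff(lncPool, negLnc)
  genePool <- if (length(geneIds)) geneIds else lncPool
  nModGene <- p$module_size - nModLnc
  modGene <- take(genePool, p$n_modules * nModGene, "module genes")
  genePool <- setdiff(genePool, modGene)
  negGene <- take(genePool, p$n_negative_pairs, "negative-pair genes")
  modules <- lapply(seq_len(p$n_modules), function(m) {
    c(modLnc[((m - 1L) * nModLnc + 1L):(m * nModLnc)],
      modGene[((m - 1L) * nModGene + 1L):(m * nModGene)])
  })
  negPairs <- data.frame(lncrna_id = negLnc, gene_id = negGene,
                         stringsAsFactors = FALSE)
  specTissue <- stats::setNames(
    rep(tissues, length.out = length(specific)), specific)
  if (is.null(baseTpm))
    baseTpm <- stats::setNames(stats::rlnorm(length(allIds),
                                             meanlog = log(10), sdlog = 1),
                               allIds)
  noise <- matrix(stats::rnorm(length(allIds) * nSamp, 0, p$noise_sd),
                  nrow = length(allIds))
  logExpr <- matrix(log2(baseTpm[allIds]), nrow = length(allIds),
                    ncol = nSamp,
                    dimnames = list(allIds, sampleIds)) + noise
  for (id in specific)
    logExpr[id, trueTissue == specTissue[id]] <-
      logExpr[id, trueTissue == specTissue[id]] + log2(p$fold)
  for (m in seq_along(modules)) {
    latent <- stats::rnorm(nSamp)
    for (id in modules[[m]])
      logExpr[id, ] <- logExpr[id, ] + p$module_amp * latent
  }
  for (k in seq_len(nrow(negPairs))) {
    latent <- stats::rnorm(nSamp)
    logExpr[negPairs$lncrna_id[k], ] <-
      logExpr[negPairs$lncrna_id[k], ] + p$neg_amp * latent
    logExpr[negPairs$gene_id[k], ] <-
      logExpr[negPairs$gene_id[k], ] - p$neg_amp * latent
  }
  mat <- 2^logExpr
  expr <- ExpressionMatrix(mat, ifelse(described, trueTissue, ""))
  truth <- list(planted_specific = specTissue,
                planted_modules = modules,
                planted_negative_pairs = negPairs,
                true_tissue = stats::setNames(trueTissue, sampleIds))
  list(expr = expr, truth = truth)
}

#' Simulate promoters with planted motif occurrences
#'
#' Uniform-random promoter sequences; a near-consensus PWM (each column puts
#' \code{colProb} on one base) whose consensus word is embedded at recorded
#' offsets and strands in a \code{hitRate} fraction of promoters.
#'
#' @param nPromoters number of promoters (default 200).
#' @param pwmWidth motif width (default 12; at width >= 10 the consensus
#'   passes the 1e-6 scan threshold).
#' @param hitRate fraction of promoters receiving a planted hit.
#' @param promoterLen promoter length (default 3000).
#' @param colProb consensus-base probability per column (default 0.97).
#' @param seed integer seed.
#' @return list with \code{promoters} (\code{DNAStringSet}), \code{pwm}
#'   (a \code{PWM}) and \code{truth} (\code{planted_motif_hits}: data.frame
#'   \code{promoter_id}, \code{offset}, \code{strand}).
#' @export
makePromotersAndMotifs <- function(nPromoters = 200L, pwmWidth = 12L,
                                   hitRate = 0.1, promoterLen = 3000L,
                                   colProb = 0.97, seed = 1L) {
  if (pwmWidth > promoterLen) stop("pwmWidth exceeds promoter length")
  if (hitRate < 0 || hitRate > 1) stop("hitRate must lie in [0, 1]")
  set.seed(.deriveSeed(seed, 4L))
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(nPromoters), function(i)
    paste(sample(bases, promoterLen, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- sprintf("P%04d", seq_len(nPromoters))
  consensus <- sample(bases, pwmWidth, replace = TRUE)
  m <- matrix((1 - colProb) / 3, nrow = 4, ncol = pwmWidth,
              dimnames = list(bases, NULL))
  for (j in seq_len(pwmWidth)) m[consensus[j], j] <- colProb
  pwm <- newPWM(m, id = "M001", pseudocount = 0)
  nHit <- round(hitRate * nPromoters)
  hits <- NULL
  if (nHit > 0L) {
    hitProms <- sample(names(seqs), nHit)
    offs <- sample(0:(promoterLen - pwmWidth), nHit, replace = TRUE)
    strands <- sample(c("+", "-"), nHit, replace = TRUE)
    word <- paste(consensus, collapse = "")
    rcWord <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(word)))
    for (k in seq_len(nHit)) {
      w <- if (strands[k] == "+") word else rcWord
      substr(seqs[hitProms[k]], offs[k] + 1L, offs[k] + pwmWidth) <- w
    }
    hits <- data.frame(promoter_id = hitProms, offset = offs,
                       strand = strands, stringsAsFactors = FALSE)
  } else {
    hits <- data.frame(promoter_id = character(0), offset = integer(0),
                       strand = character(0))
  }
  list(promoters = Biostrings::DNAStringSet(seqs), pwm = pwm,
       truth = list(planted_motif_hits = hits))
}

#' Simulate reciprocal alignment hit tables with planted orthologs
#'
#' Planted pairs are mutual best hits with e-values drawn in
#' [1e-120, 1e-60]; decoy hits rank strictly worse and are arranged never to
#' be mutual, so the primary reciprocal-best-hit tier recovers exactly the
#' planted pairs.
#'
#' @param nA,nB protein counts in the two sets.
#' @param nOrthologs planted ortholog pairs (<= min(nA, nB)).
#' @param seed integer seed.
#' @return list with \code{hitsAB}, \code{hitsBA} (hit tables) and
#'   \code{truth} (\code{planted_orthologs}: data.frame \code{id_a},
#'   \code{id_b}).
#' @export
makeOrthologScores <- function(nA = 60L, nB = 60L, nOrthologs = 20L,
                               seed = 1L) {
  if (nOrthologs > min(nA, nB)) stop("nOrthologs exceeds min(nA, nB)")
  set.seed(.deriveSeed(seed, 5L))
  idsA <- sprintf("a%03d", seq_len(nA))
  idsB <- sprintf("b%03d", seq_len(nB))
  row <- function(q, s, e, bit)
    data.frame(query_id = q, subject_id = s, percent_identity = 60,
               alignment_length = 200, mismatches = 0, gap_opens = 0,
               q_start = 1, q_end = 200, s_start = 1, s_end = 200,
               e_value = e, bit_score = bit, stringsAsFactors = FALSE)
  ab <- list(); ba <- list()
  for (k in seq_len(nOrthologs)) {
    e <- 10^(-stats::runif(1, 60, 120))
    ab[[length(ab) + 1L]] <- row(idsA[k], idsB[k], e, 900)
    ba[[length(ba) + 1L]] <- row(idsB[k], idsA[k], e, 900)
    ## decoy 2nd/3rd hits, strictly worse
    dec <- setdiff(sample(idsB, 3L), idsB[k])[1:2]
    ab[[length(ab) + 1L]] <- row(idsA[k], dec[1L], 10^(-stats::runif(1, 20, 40)), 300)
    ab[[length(ab) + 1L]] <- row(idsA[k], dec[2L], 10^(-stats::runif(1, 5, 15)), 150)
  }
  ## non-ortholog queries: best hits point at planted subjects (never mutual)
  if (nOrthologs < nA && nOrthologs >= 1L)
    for (k in (nOrthologs + 1L):nA)
      ab[[length(ab) + 1L]] <- row(idsA[k], idsB[1L],
                                   10^(-stats::runif(1, 3, 8)), 80)
  if (nOrthologs < nB && nOrthologs >= 1L)
    for (k in (nOrthologs + 1L):nB)
      ba[[length(ba) + 1L]] <- row(idsB[k], idsA[1L],
                                   10^(-stats::runif(1, 3, 8)), 80)
  list(hitsAB = do.call(rbind, ab), hitsBA = do.call(rbind, ba),
       truth = list(planted_orthologs = data.frame(
         id_a = idsA[seq_len(nOrthologs)], id_b = idsB[seq_len(nOrthologs)],
         stringsAsFactors = FALSE)))
}

#' Simulate every input of the identification + annotation pipeline
#'
#' Orchestrates \code{\link{makeGenome}}, \code{\link{makeAssembly}} and
#' \code{\link{makeExpression}} into one consistent world: expression rows
#' cover the merged assembly representatives plus the reference coding genes,
#' baseline TPM and recurrence are planted per category (reference-identical
#' transcripts high, intronic/artifact transcripts low — the separation the
#' contamination classifier learns), and a GO table assigns each planted
#' module's genes a shared term (the first module's term is named for
#' secondary-cell-wall biogenesis so keyword mining has a planted target).
#'
#' @param seed integer seed.
#' @param nGenes,nTranscripts,nSamples scale knobs passed through.
#' @return list with components \code{genome}, \code{annotation},
#'   \code{organelleBed}, \code{assembly}, \code{ncrnaBed}, \code{simHits},
#'   \code{domainHits}, \code{expr}, \code{goTable}, \code{termNames} and
#'   \code{truth} (the union of all planted truth).
#' @export
simulatePipelineData <- function(seed = 1L, nGenes = 200L,
                                 nTranscripts = 200L, nSamples = 60L) {
  gen <- makeGenome(nGenes = nGenes, seed = seed)
  asm <- makeAssembly(gen, nTranscripts = nTranscripts, nSamples = nSamples,
                      seed = seed)
  truth <- asm$truth
  geneIdsAll <- sort(unique(gen$annotation@txData$gene_id))
  ## baseline TPM per category: "=" and genes high; i/artifact low
  repIds <- truth$rep_id
  cat <- truth$category
  set.seed(.deriveSeed(seed, 6L))
  baseOf <- function(cats) vapply(cats, function(cc) switch(cc,
    ref_equal = stats::rlnorm(1, log(40), 0.5),
    intronic = stats::rlnorm(1, log(0.4), 0.3),
    artifact = stats::rlnorm(1, log(0.4), 0.3),
    stats::rlnorm(1, log(15), 0.5)), numeric(1))
  baseTpm <- c(stats::setNames(baseOf(cat), unname(repIds)),
               stats::setNames(stats::rlnorm(length(geneIdsAll),
                                             log(30), 0.6), geneIdsAll))
  ## lncRNA representatives host the planted expression structure
  lncReps <- unname(repIds[truth$category == "lncRNA"])
  otherReps <- setdiff(unname(repIds), lncReps)
  ex <- makeExpression(ids = c(lncReps, otherReps), geneIds = geneIdsAll,
                       baseTpm = baseTpm, seed = seed)
  ## GO table: module genes share a term. The first three module terms are
  ## named targets for downstream mining: secondary cell wall (keyword
  ## selection), flavonoid and lignin biosynthesis (pathway preference).
  nMod <- length(ex$truth$planted_modules)
  namedTerms <- c("GO:0990001" = "secondary cell wall biogenesis",
                  "GO:0009813" = "flavonoid biosynthetic process",
                  "GO:0009809" = "lignin biosynthetic process")
  modTerms <- c(names(namedTerms),
                sprintf("GO:09%05d", seq_len(max(0L, nMod - 3L))))[
                  seq_len(nMod)]
  termNames <- stats::setNames(
    c(unname(namedTerms),
      paste("synthetic process", seq_len(max(0L, nMod - 3L))))[seq_len(nMod)],
    modTerms)
  goTable <- list()
  for (m in seq_along(ex$truth$planted_modules)) {
    for (g in intersect(ex$truth$planted_modules[[m]], geneIdsAll))
      goTable[[g]] <- c(goTable[[g]], modTerms[m])
  }
  ## scatter uninformative terms over remaining genes
  rest <- setdiff(geneIdsAll, names(goTable))
  for (g in rest) goTable[[g]] <- sprintf("GO:0%06d", sample.int(99999, 1L))
  list(genome = gen$genome, annotation = gen$annotation,
       organelleBed = gen$organelleBed, assembly = asm$assembly,
       ncrnaBed = asm$ncrnaBed, simHits = asm$simHits,
       domainHits = asm$domainHits, expr = ex$expr, goTable = goTable,
       termNames = termNames,
       truth = c(truth, ex$truth))
}
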