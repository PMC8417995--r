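#' Run the lncRNA identification pipeline end to end
#'
#' Chains the identification stages in the published order: organelle and
#' known-ncRNA overlap filters, per-sample merging, class-code assignment
#' against the reference, retention of the j/u/x/o codes, the two-classifier
#' contamination filter (trained on the "=" versus "i" assembly features of
#' this very assembly), and the coding-ability cascade
#' (similarity, length, coding potential, domain).
#'
#' @param assembly \code{TranscriptSet} of per-sample assembled transcripts.
#' @param reference \code{TranscriptSet} genome annotation.
#' @param genome named \code{DNAStringSet}.
#' @param expr expression container with one row per merged representative.
#' @param organelleBed,ncrnaBed \code{GRanges} interval sets.
#' @param simHits,domainHits hit tables for the coding cascade (may be NULL).
#' @param thresholds see \code{\link{filterThresholds}}.
#' @param rule contamination-filter combination rule.
#' @param seed integer seed (classifier training).
#' @return list: \code{lncrna} (surviving \code{TranscriptSet}),
#'   \code{lncrnaIds}, \code{merged}, \code{classCodes}, \code{model},
#'   \code{logs} (per-stage removal records).
#' @export
runIdentification <- function(assembly, reference, genome, expr,
                              organelleBed = GenomicRanges::GRanges(),
                              ncrnaBed = GenomicRanges::GRanges(),
                              simHits = NULL, domainHits = NULL,
                              thresholds = filterThresholds(),
                              rule = "both_agree", seed = 1L) {
  ov <- organelleNcrnaFilter(assembly, organelleBed, ncrnaBed, thresholds)
  mg <- mergeTranscripts(ov$kept)
  codes <- classCodes(mg$merged, reference)
  feats <- extractFeatures(mg$merged, expr)
  eqIds <- names(codes)[codes == "="]
  inIds <- names(codes)[codes == "i"]
  model <- trainContaminationFilter(feats[eqIds, , drop = FALSE],
                                    feats[inIds, , drop = FALSE],
                                    rule = rule, seed = seed)
  candIds <- names(codes)[codes %in% thresholds$retained_codes]
  ml <- applyContaminationFilter(model, feats[candIds, , drop = FALSE])
  seqs <- transcriptSequences(mg$merged[ml$kept], genome)
  cascade <- codingAbilityCascade(ml$kept, seqs, simHits, domainHits,
                                  thresholds)
  list(lncrna = mg$merged[cascade$lncrna],
       lncrnaIds = cascade$lncrna,
       merged = mg, classCodes = codes, model = model,
       logs = list(overlap = ov$log,
                   ml_removed = ml$removed,
                   cascade = cascade$log,
                   cascade_removals = cascade$removals))
}

#' Run the three-channel functional annotation
#'
#' Tissue specificity (Tau/TSI over described samples), adjacent coding
#' genes (< 100 kb), and TOM co-expression with per-lncRNA GSEA over the
#' supplied GO gene sets; channels are combined with union semantics.
#'
#' @param lncrna \code{TranscriptSet} of identified lncRNAs.
#' @param reference genome annotation \code{TranscriptSet}.
#' @param expr expression container holding lncRNA and coding-gene rows.
#' @param geneIds coding-gene row ids used for co-expression/GSEA.
#' @param goTable named list gene -> GO ids (NULL disables the channel).
#' @param tauThreshold,tomThreshold,padjThreshold call thresholds (0.95,
#'   0.1, 0.005).
#' @param beta soft-threshold exponent for \code{\link{buildTom}}.
#' @param nPerm GSEA permutations per lncRNA.
#' @param seed integer seed.
#' @return list: \code{annotations} (see \code{\link{combineAnnotations}}),
#'   \code{tissue}, \code{adjacent}, \code{enrichment}, \code{tom}.
#' @export
runAnnotation <- function(lncrna, reference, expr, geneIds,
                          goTable = NULL, tauThreshold = 0.95,
                          tomThreshold = 0.1, padjThreshold = 0.005,
                          beta = 6, nPerm = 500L, seed = 1L) {
  ids <- transcriptIds(lncrna)
  tissue <- callTissueSpecific(expr, tauThreshold, rowIds = ids)
  adjacent <- annotateAdjacentGenes(lncrna, reference)
  m <- tpm(expr)
  geneIds <- intersect(geneIds, rownames(m))
  tom <- buildTom(m[c(ids, geneIds), , drop = FALSE], beta = beta)
  enrichment <- NULL
  if (!is.null(goTable)) {
    tm <- tomMatrix(tom)
    rows <- list()
    for (i in seq_along(ids)) {
      id <- ids[i]
      if (!id %in% rownames(tm)) next
      partners <- coexpressionPartners(tom, id, tomThreshold)
      if (!length(intersect(names(partners), geneIds))) next
      ranking <- tm[id, intersect(geneIds, colnames(tm))]
      res <- gseaAnnotate(ranking, goTable2sets(goTable), nPerm = nPerm,
                          seed = .deriveSeed(seed, i))
      ## annotate only by positively enriched sets: genes drawn toward the
      ## top of the lncRNA's co-expression ranking
      sig <- res[res$padj < padjThreshold & res$es > 0, , drop = FALSE]
      if (nrow(sig)) {
        sig$lncrna_id <- id
        rows[[length(rows) + 1L]] <- sig
      }
    }
    enrichment <- do.call(rbind, rows)
  }
  annotations <- combineAnnotations(ids, tissue = tissue,
                                    adjacent = adjacent,
                                    coexpression = enrichment)
  list(annotations = annotations, tissue = tissue, adjacent = adjacent,
       enrichment = enrichment, tom = tom)
}

#' Invert a gene -> GO table into GO -> gene sets
#' @param goTable named list gene -> character vector of GO ids.
#' @return named list GO id -> character vector of genes.
#' @export
goTable2sets <- function(goTable) {
  pairs <- data.frame(
    gene = rep(names(goTable), lengths(goTable)),
    term = unlist(goTable, use.names = FALSE), stringsAsFactors = FALSE)
  split(pairs$gene, pairs$term)
}
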