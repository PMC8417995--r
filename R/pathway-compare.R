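#' Default flavonoid- and lignin-pathway GO term sets
#'
#' Flavonoid: GO:0009812 (flavonoid metabolic process), GO:0009813
#' (flavonoid biosynthetic process), GO:0009962 / GO:0009963 / GO:0009964
#' (regulation, positive and negative regulation of flavonoid biosynthesis)
#' and GO:1903415 (flavonoid transport from ER to the plant-type vacuole).
#' Lignin: GO:0009808 (lignin metabolic process), GO:0009809 (lignin
#' biosynthetic process), GO:0046274 (lignin catabolic process) and
#' GO:1901141 (regulation of lignin biosynthesis). Terms are used as flat
#' sets with no ancestor propagation.
#'
#' @return list with character vectors \code{flavonoid} and \code{lignin}.
#' @export
defaultPathwayTerms <- function() {
  list(flavonoid = c("GO:0009812", "GO:0009813", "GO:0009962", "GO:0009963",
                     "GO:0009964", "GO:1903415"),
       lignin = c("GO:0009808", "GO:0009809", "GO:0046274", "GO:1901141"))
}

#' Tag the co-expression partners of a gene by pathway
#'
#' Partners at TOM strictly greater than the threshold (restricted to coding
#' genes when \code{codingIds} is given) whose GO annotations intersect the
#' flavonoid / lignin term sets; a partner annotated with both appears in
#' both lists.
#'
#' @param geneId query gene (must be a node of \code{tomNet}).
#' @param tomNet a \linkS4class{TomNetwork}.
#' @param goTable named list: gene -> character vector of GO ids.
#' @param termSets list with \code{flavonoid} and \code{lignin} id sets
#'   (default \code{\link{defaultPathwayTerms}}).
#' @param threshold TOM edge threshold (default 0.1, strict >).
#' @param codingIds optional coding-gene universe; partners outside it are
#'   ignored.
#' @return list with \code{flavonoid} and \code{lignin} partner id vectors.
#' @export
tagPartners <- function(geneId, tomNet, goTable,
                        termSets = defaultPathwayTerms(), threshold = 0.1,
                        codingIds = NULL) {
  partners <- names(coexpressionPartners(tomNet, geneId, threshold))
  if (!is.null(codingIds)) partners <- intersect(partners, codingIds)
  gos <- goTable[partners]
  hasAny <- function(terms) partners[vapply(gos, function(g)
    !is.null(g) && any(g %in% terms), logical(1))]
  list(flavonoid = hasAny(termSets$flavonoid),
       lignin = hasAny(termSets$lignin))
}

#' Classify genes as flavonoid-preferred, lignin-preferred, dual or none
#'
#' A gene is \code{flavonoid_preferred} iff it has flavonoid-tagged
#' co-expression partners and no lignin-tagged ones, \code{lignin_preferred}
#' in the mirror case, \code{dual} with both, \code{none} with neither.
#'
#' @param geneIds query gene ids (e.g. PAL/C4H/4CL family members).
#' @param tagged named list: gene id -> output of \code{\link{tagPartners}}.
#' @return list with \code{calls} (data.frame \code{gene_id},
#'   \code{n_flavonoid_partners}, \code{n_lignin_partners}, \code{label}) and
#'   \code{summary} (label counts; sums to length(geneIds)).
#' @export
classifyPreference <- function(geneIds, tagged) {
  calls <- do.call(rbind, lapply(geneIds, function(g) {
    tg <- tagged[[g]]
    nf <- if (is.null(tg)) 0L else length(tg$flavonoid)
    nl <- if (is.null(tg)) 0L else length(tg$lignin)
    label <- if (nf > 0 && nl == 0) "flavonoid_preferred"
      else if (nl > 0 && nf == 0) "lignin_preferred"
      else if (nf > 0 && nl > 0) "dual" else "none"
    data.frame(gene_id = g, n_flavonoid_partners = nf,
               n_lignin_partners = nl, label = label,
               stringsAsFactors = FALSE)
  }))
  lv <- c("flavonoid_preferred", "lignin_preferred", "dual", "none")
  list(calls = calls,
       summary = table(factor(calls$label, levels = lv)))
}
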