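## tiny constructors -------------------------------------------------------

## txset("t1", "chr1", "+", list(c(101, 200), c(301, 400)), gene = "g1", ...)
txset <- function(...) {
  args <- list(...)
  exl <- list(); genes <- character(0); samples <- character(0)
  for (tx in args) {
    exl[[tx$id]] <- GenomicRanges::GRanges(
      tx$chrom,
      IRanges::IRanges(vapply(tx$exons, `[`, numeric(1), 1L),
                       vapply(tx$exons, `[`, numeric(1), 2L)),
      strand = tx$strand)
    genes <- c(genes, if (is.null(tx$gene)) tx$id else tx$gene)
    samples <- c(samples, if (is.null(tx$sample)) "" else tx$sample)
  }
  TranscriptSet(GenomicRanges::GRangesList(exl), genes, samples)
}

tx <- function(id, chrom, strand, exons, gene = NULL, sample = NULL)
  list(id = id, chrom = chrom, strand = strand, exons = exons, gene = gene,
       sample = sample)

randomDna <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## independent class-code oracle ------------------------------------------
## plain-integer re-derivation of the rule table; shares no code with the
## package implementation
oracleClassCode <- function(qStarts, qEnds, qStrand, refs) {
  ## refs: list of list(starts, ends, strand); all on one contig
  nq <- length(qStarts)
  qIntrons <- if (nq > 1)
    paste(qEnds[-nq] + 1, qStarts[-1] - 1) else character(0)
  ovBp <- function(s1, e1, s2, e2) {
    tot <- 0
    for (i in seq_along(s1)) for (j in seq_along(s2))
      tot <- tot + max(0, min(e1[i], e2[j]) - max(s1[i], s2[j]) + 1)
    tot
  }
  qLen <- sum(qEnds - qStarts + 1)
  isEq <- isJ <- isI <- isX <- isO <- FALSE
  for (r in refs) {
    nr <- length(r$starts)
    same <- r$strand == qStrand
    ov <- ovBp(qStarts, qEnds, r$starts, r$ends)
    rIntrons <- if (nr > 1)
      paste(r$ends[-nr] + 1, r$starts[-1] - 1) else character(0)
    if (same && nq > 1 && nr > 1 && length(qIntrons) == length(rIntrons) &&
        all(qIntrons == rIntrons))
      isEq <- TRUE
    if (same && nq == 1 && nr == 1 && ov > 0) {
      rLen <- r$ends[1] - r$starts[1] + 1
      if (ov / qLen >= 0.95 && ov / rLen >= 0.95) isEq <- TRUE
    }
    if (same && length(intersect(qIntrons, rIntrons)) > 0) isJ <- TRUE
    if (same && nr > 1) {
      for (k in seq_len(nr - 1))
        if (r$ends[k] + 1 <= min(qStarts) && max(qEnds) <= r$starts[k + 1] - 1)
          isI <- TRUE
    }
    if (!same && ov > 0) isX <- TRUE
    if (same && ov > 0) isO <- TRUE
  }
  if (isEq) return("=")
  if (isJ) return("j")
  if (isI) return("i")
  if (isX) return("x")
  if (isO) return("o")
  "u"
}

## deterministic enumeration of 2-transcript geometries with <= 3 exons,
## coordinates drawn from a coarse grid
enumerateGeometries <- function(n = 400, seed = 42) {
  set.seed(seed)
  grid <- seq(10, 400, by = 30)
  mkTx <- function() {
    k <- sample(1:3, 1)
    bounds <- sort(sample(grid, 2 * k))
    list(starts = bounds[seq(1, 2 * k, 2)], ends = bounds[seq(2, 2 * k, 2)],
         strand = sample(c("+", "-"), 1))
  }
  lapply(seq_len(n), function(i) list(query = mkTx(), ref = mkTx()))
}

## brute-force O(n^3) topological overlap oracle ---------------------------
oracleTom <- function(mat, beta = 6) {
  a <- abs(stats::cor(t(mat)))^beta
  diag(a) <- 0
  n <- nrow(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    tom[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

## shared end-to-end simulation, built once per test run -------------------
.e2eCache <- new.env()
e2eWorld <- function() {
  if (is.null(.e2eCache$sim)) {
    .e2eCache$sim <- simulatePipelineData(seed = 101)
    .e2eCache$res <- runIdentification(
      .e2eCache$sim$assembly, .e2eCache$sim$annotation, .e2eCache$sim$genome,
      .e2eCache$sim$expr, .e2eCache$sim$organelleBed, .e2eCache$sim$ncrnaBed,
      .e2eCache$sim$simHits, .e2eCache$sim$domainHits, seed = 101)
  }
  list(sim = .e2eCache$sim, res = .e2eCache$res)
}
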