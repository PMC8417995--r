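ref3 <- txset(
  tx("r1", "chr1", "+", list(c(100, 200), c(300, 400), c(500, 600)),
     gene = "gA"),
  tx("r2", "chr1", "-", list(c(1000, 1200)), gene = "gB"))

test_that("class codes follow the published definitions and precedence", {
  q <- function(chrom, strand, exons)
    GenomicRanges::GRanges(chrom,
      IRanges::IRanges(vapply(exons, `[`, numeric(1), 1),
                       vapply(exons, `[`, numeric(1), 2)), strand = strand)
  ## identical intron chain -> "="
  expect_equal(assignClassCode(
    q("chr1", "+", list(c(90, 200), c(300, 400), c(500, 650))), ref3), "=")
  ## shares junction 1 of 2 -> "j"
  expect_equal(assignClassCode(
    q("chr1", "+", list(c(120, 200), c(300, 450))), ref3), "j")
  ## mono-exonic inside intron, same strand -> "i"
  expect_equal(assignClassCode(q("chr1", "+", list(c(220, 280))), ref3), "i")
  ## inside intron on the OPPOSITE strand: no exonic overlap, not
  ## same-strand intronic -> resolves to "u" by precedence
  expect_equal(assignClassCode(q("chr1", "-", list(c(220, 280))), ref3), "u")
  ## exonic overlap opposite strand -> "x"
  expect_equal(assignClassCode(q("chr1", "-", list(c(150, 250))), ref3), "x")
  ## same-strand exonic overlap, no shared junction -> "o"
  expect_equal(assignClassCode(q("chr1", "+", list(c(150, 250))), ref3), "o")
  ## disjoint -> "u"
  expect_equal(assignClassCode(q("chr1", "+", list(c(5000, 5400))), ref3), "u")
  ## mono-exonic reciprocal overlap >= 0.95 same strand -> "="
  expect_equal(assignClassCode(q("chr1", "-", list(c(1001, 1200))), ref3), "=")
  ## reciprocal overlap below 0.95 -> "o"
  expect_equal(assignClassCode(q("chr1", "-", list(c(1100, 1300))), ref3), "o")
  ## unknown contig errors
  expect_error(assignClassCode(q("chr9", "+", list(c(1, 50))), ref3),
               "chr9")
})

test_that("assignClassCode agrees with the rule-table oracle on enumerated
          geometries", {
  cases <- enumerateGeometries(n = 300, seed = 7)
  for (cs in cases) {
    ref <- txset(list(id = "r", chrom = "c1", strand = cs$ref$strand,
                      exons = Map(c, cs$ref$starts, cs$ref$ends),
                      gene = "g", sample = NULL))
    got <- assignClassCode(GenomicRanges::GRanges(
      "c1", IRanges::IRanges(cs$query$starts, cs$query$ends),
      strand = cs$query$strand), ref)
    want <- oracleClassCode(cs$query$starts, cs$query$ends, cs$query$strand,
                            list(cs$ref))
    expect_equal(got, want)
  }
})

test_that("overlapRatio is exonic-bp intersection over exonic length", {
  ts <- txset(tx("t", "chr1", "+", list(c(1, 1000))))
  expect_equal(overlapRatio(ts, GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(201, 1000))), 0.8)
  expect_equal(overlapRatio(ts, GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(5000, 6000))), 0)
  expect_equal(overlapRatio(ts, GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1, 2000))), 1)
  ## strand-agnostic
  expect_equal(overlapRatio(ts, GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(201, 1000), strand = "-")), 0.8)
})

test_that("organelle/ncRNA filters remove on strictly greater ratios", {
  ## exonic length 1000; organelle interval covers 740 / 750 / 760 bp
  ts <- txset(tx("t74", "chrC", "+", list(c(1, 1000))),
              tx("t75", "chrC", "+", list(c(2001, 3000))),
              tx("t76", "chrC", "+", list(c(4001, 5000))),
              tx("n30", "chr1", "+", list(c(1, 1000))),
              tx("n31", "chr1", "+", list(c(2001, 3000))))
  org <- GenomicRanges::GRanges("chrC", IRanges::IRanges(
    c(1, 2001, 4001), c(740, 2750, 4760)))
  nc <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(1, 2001), c(300, 2310)))
  out <- organelleNcrnaFilter(ts, org, nc)
  expect_setequal(transcriptIds(out$kept), c("t74", "t75", "n30"))
  expect_setequal(out$log$transcript_id, c("t76", "n31"))
  expect_equal(out$log$filter[out$log$transcript_id == "t76"], "organelle")
  ## empty interval sets are the identity
  id <- organelleNcrnaFilter(ts, GenomicRanges::GRanges(),
                             GenomicRanges::GRanges())
  expect_equal(length(id$kept), length(ts))
  expect_equal(nrow(id$log), 0L)
})

test_that("merging collapses identical transcripts and counts loci", {
  ts <- txset(
    tx("a_s1", "chr1", "+", list(c(100, 200), c(300, 400)), sample = "s1"),
    tx("a_s2", "chr1", "+", list(c(100, 200), c(300, 400)), sample = "s2"),
    tx("a_s3", "chr1", "+", list(c(100, 200), c(300, 400)), sample = "s3"),
    tx("b_s1", "chr1", "-", list(c(150, 350)), sample = "s1"),
    tx("c_s1", "chr1", "+", list(c(5000, 5500)), sample = "s1"),
    tx("c_s2", "chr1", "+", list(c(5001, 5501)), sample = "s2"))
  mg <- mergeTranscripts(ts)
  td <- txData(mg$merged)
  ## identical multi-exon copies collapse with recurrence 3
  aRep <- td$transcript_id[startsWith(td$transcript_id, "a_")]
  expect_length(aRep, 1L)
  expect_equal(td$recurrence[td$transcript_id == aRep], 3L)
  ## near-identical mono-exonic transcripts (reciprocal overlap >= 0.95)
  cRep <- td$transcript_id[startsWith(td$transcript_id, "c_")]
  expect_length(cRep, 1L)
  expect_equal(td$recurrence[td$transcript_id == cRep], 2L)
  ## strand-opposite overlap does NOT share a locus: a and b form 2 loci,
  ## c a third
  expect_equal(length(unique(td$locus)), 3L)
})

test_that("extractFeatures computes the five features", {
  ts <- txset(tx("t1", "chr1", "+", list(c(1, 60), c(101, 140)), sample = "s1"))
  mg <- mergeTranscripts(ts)
  m <- matrix(c(0, 0, 6), nrow = 1,
              dimnames = list("t1", c("s1", "s2", "s3")))
  se <- ExpressionMatrix(m)
  f <- extractFeatures(mg$merged, se)
  expect_equal(unname(f["t1", ]),
               c(1 / 3, 6, 2, 100, 2))
  ## missing row errors with the id
  ts2 <- txset(tx("zz", "chr1", "+", list(c(1, 50)), sample = "s1"))
  expect_error(extractFeatures(mergeTranscripts(ts2)$merged, se), "zz")
})

test_that("contamination filter separates planted feature classes", {
  mkFeat <- function(n, recur, tpmMu, len, seed) {
    set.seed(seed)
    cbind(recurrence_ratio = pmin(1, pmax(0, rnorm(n, recur, 0.05))),
          max_tpm = rlnorm(n, log(tpmMu), 0.3),
          mean_tpm = rlnorm(n, log(tpmMu / 3), 0.3),
          length = rlnorm(n, log(len), 0.2),
          exon_count = sample(1:6, n, replace = TRUE))
  }
  accs <- vapply(1:5, function(s) {
    eq <- mkFeat(60, 0.5, 40, 1000, s)
    intr <- mkFeat(60, 0.05, 0.5, 250, s + 100)
    model <- trainContaminationFilter(eq, intr, seed = s)
    model@trainSummary$heldout_accuracy
  }, numeric(1))
  expect_true(all(accs >= 0.95))
  ## identical class distributions -> chance-level held-out accuracy
  set.seed(9)
  accNull <- vapply(1:5, function(s) {
    both <- mkFeat(120, 0.3, 5, 500, s + 200)
    m <- trainContaminationFilter(both[1:60, ], both[61:120, ], seed = s)
    m@trainSummary$heldout_accuracy
  }, numeric(1))
  expect_true(mean(accNull) > 0.3 && mean(accNull) < 0.7)
  ## determinism: identical predictions for a fixed seed
  eq <- mkFeat(40, 0.5, 40, 1000, 1); intr <- mkFeat(40, 0.05, 0.5, 250, 2)
  probe <- mkFeat(20, 0.2, 5, 500, 3)
  m1 <- trainContaminationFilter(eq, intr, seed = 5)
  m2 <- trainContaminationFilter(eq, intr, seed = 5)
  expect_identical(predictContamination(m1, probe),
                   predictContamination(m2, probe))
  ## guards
  expect_error(trainContaminationFilter(eq[1:5, ], intr), "20")
  expect_error(trainContaminationFilter(eq[0, ], intr), "empty")
})

test_that("combination rules merge disagreeing classifiers as specified", {
  ## forest stub always predicts intronic_like; margin trained to separate
  ## on feature 1 so an equal-side probe yields disagreement
  set.seed(3)
  X <- cbind(f1 = c(rnorm(30, 5), rnorm(30, -5)), f2 = rnorm(60))
  y <- c(rep(0L, 30), rep(1L, 30))
  margin <- lncscape:::.marginFit(X, y)
  forest <- list(list(leaf = TRUE, p = 1))   # always intronic
  mkModel <- function(rule)
    new("ContaminationModel", forest = forest, margin = margin, rule = rule,
        featureNames = colnames(X),
        trainSummary = list(n_equal = 30, n_intronic = 30,
                            heldout_accuracy = NA_real_),
        fitted = TRUE)
  probe <- matrix(c(6, 0), nrow = 1, dimnames = list("p1", colnames(X)))
  bothAgree <- applyContaminationFilter(mkModel("both_agree"), probe)
  expect_equal(bothAgree$kept, "p1")      # disagreement -> kept
  either <- applyContaminationFilter(mkModel("either"), probe)
  expect_equal(either$removed, "p1")      # disagreement -> removed
  expect_equal(applyContaminationFilter(mkModel("forest_only"), probe)$removed,
               "p1")
  expect_equal(applyContaminationFilter(mkModel("margin_only"), probe)$kept,
               "p1")
  ## unfitted model refuses
  unfit <- mkModel("both_agree"); unfit@fitted <- FALSE
  expect_error(applyContaminationFilter(unfit, probe), "fitted")
})

test_that("ORF finder and verdict rule behave on constructed sequences", {
  ## no ATG -> no ORF, noncoding
  res <- scoreCodingPotential("CCTTCCGGTTCCGGTTCC")
  expect_equal(res$longest_orf_aa, 0L)
  expect_equal(res$verdict, "noncoding")
  ## ATG + 119 sense codons + TAA embedded in ~400 nt -> 120 aa, coding
  set.seed(21)
  sense <- c("GCT", "GGA", "TCC", "CTG", "AAA", "GTC", "CAT")
  orf <- paste0("ATG", paste(sample(sense, 119, TRUE), collapse = ""), "TAA")
  pad1 <- "CCCC"   # shifts the ORF out of frame 0 of the transcript
  pad2 <- substr(randomDna(40, 5), 1, 37)
  seqc <- paste0(pad1, orf, pad2)
  res <- scoreCodingPotential(seqc)
  expect_equal(res$longest_orf_aa, 120L)
  expect_equal(res$verdict, "coding")
  ## coverage is ORF nt over sequence nt
  expect_equal(res$orf_coverage, 360 / nchar(seqc))
  ## invalid characters rejected
  expect_error(scoreCodingPotential("ACGU"), "A/C/G/T/N")
})

test_that("random sequences rarely earn a coding verdict", {
  set.seed(31)
  n <- 400
  verdicts <- vapply(seq_len(n), function(i)
    scoreCodingPotential(randomDna(300, seed = 1000 + i))$verdict,
    character(1))
  expect_lte(mean(verdicts == "coding"), 0.10)
})

test_that("the coding cascade applies its four stages in order", {
  seqs <- Biostrings::DNAStringSet(c(
    a = randomDna(400, 1), b = randomDna(400, 2), c = randomDna(149, 3),
    d = randomDna(400, 4), e = randomDna(150, 5)))
  sim <- data.frame(query_id = c("a", "b"), subject_id = c("x", "y"),
                    percent_identity = c(40, 90),
                    alignment_length = c(45, 39),
                    e_value = c(1e-5, 1e-5), bit_score = c(100, 100),
                    stringsAsFactors = FALSE)
  dom <- data.frame(query_id = "d", subject_id = "PF1",
                    percent_identity = 50, alignment_length = 100,
                    e_value = 1e-5, bit_score = 80, stringsAsFactors = FALSE)
  out <- codingAbilityCascade(c("a", "b", "c", "d", "e"), seqs, sim, dom)
  ## a: all three similarity conditions met -> removed;
  ## b: alignment length fails -> NOT removed by similarity;
  ## c: length 149 < 150 -> removed; e: length 150 -> kept;
  ## d: domain hit -> removed
  expect_equal(out$removals$stage[out$removals$transcript_id == "a"],
               "similarity")
  expect_equal(out$removals$stage[out$removals$transcript_id == "c"],
               "length")
  expect_equal(out$removals$stage[out$removals$transcript_id == "d"],
               "domain")
  expect_setequal(out$lncrna, c("b", "e"))
  ## contraction + unique stage attribution
  expect_true(all(out$lncrna %in% c("a", "b", "c", "d", "e")))
  expect_false(anyDuplicated(out$removals$transcript_id) > 0)
  ## missing sequence errors
  expect_error(codingAbilityCascade(c("a", "zz"), seqs), "zz")
})
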