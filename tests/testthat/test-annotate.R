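test_that("Tau matches closed forms and is scale invariant", {
  expect_equal(computeTau(c(0, 0, 10)), 1)
  expect_equal(computeTau(c(5, 5, 5)), 0)
  expect_equal(computeTau(c(2, 4, 8)), 0.625)
  expect_true(is.na(computeTau(c(0, 0, 0))))
  ## scale invariance over generated profiles
  set.seed(4)
  for (i in 1:20) {
    x <- rexp(sample(3:10, 1))
    cc <- runif(1, 0.01, 100)
    expect_equal(computeTau(cc * x), computeTau(x))
  }
  ## 0 iff constant, 1 iff one-hot
  expect_gt(computeTau(c(1, 1, 1.0001)), 0)
  expect_lt(computeTau(c(1e-9, 0, 5)), 1)
  expect_error(computeTau(5), "length")
})

test_that("TSI fractions, argmax and tie handling", {
  ts <- computeTsi(c(s1 = 2, s2 = 4, s3 = 8))
  expect_equal(sum(ts$tsi), 1)
  expect_equal(ts$top_tsi, 8 / 14)
  expect_equal(ts$top_sample, "s3")
  expect_false(ts$tie)
  tie <- computeTsi(c(sB = 1, sA = 1))
  expect_true(tie$tie)
  expect_equal(tie$top_sample, "sA")   # lexicographically smallest
  oneHot <- computeTsi(c(a = 0, b = 3, c = 0))
  expect_equal(oneHot$top_tsi, 1)
})

test_that("tissue-specific calling is strict at Tau = 0.95 and uses the
          top-TSI sample's description", {
  ## row 'exact' has Tau exactly 0.95: 1 max + 20 samples at 0.05 of max
  m <- rbind(exact = c(1, rep(0.05, 20)),
             spec = c(1, rep(0.001, 20)),
             flat = rep(2, 21),
             zero = rep(0, 21))
  colnames(m) <- sprintf("s%02d", 1:21)
  tissues <- c("shoot", rep(c("root", "leaf"), 10))
  se <- ExpressionMatrix(m, tissues)
  expect_equal(computeTau(m["exact", ]), 0.95)
  res <- callTissueSpecific(se)
  expect_false(res$specific[res$lncrna_id == "exact"])  # strict >
  expect_true(res$specific[res$lncrna_id == "spec"])
  expect_equal(res$tissue[res$lncrna_id == "spec"], "shoot")
  expect_false(res$specific[res$lncrna_id == "flat"])
  expect_true(is.na(res$tau[res$lncrna_id == "zero"]))
  ## undescribed samples are excluded before scoring
  m2 <- rbind(r1 = c(100, 1, 1, 1, 1, 1, 100, 100))
  colnames(m2) <- sprintf("s%d", 1:8)
  se2 <- ExpressionMatrix(m2, c("shoot", "root", "leaf", "stem", "bud",
                                "seed", "", ""))
  res2 <- callTissueSpecific(se2)
  expect_true(res2$specific)      # high undescribed samples don't count
  expect_equal(res2$tissue, "shoot")
  ## fewer than 2 described samples: warning, no calls
  se3 <- ExpressionMatrix(m2, c("shoot", rep("", 7)))
  expect_warning(res3 <- callTissueSpecific(se3), "described")
  expect_equal(nrow(res3), 0L)
})

test_that("adjacent genes within 100 kb, ranked by span gap", {
  ref <- txset(
    tx("g1.t", "chr1", "+", list(c(200000, 201000)), gene = "g1"),
    tx("g2.t", "chr1", "-", list(c(241001, 242000)), gene = "g2"),
    tx("g3.t", "chr1", "+", list(c(400000, 401000)), gene = "g3"),
    tx("g4.t", "chr1", "+", list(c(195000, 200500)), gene = "g4"))
  lnc <- txset(tx("L1", "chr1", "+", list(c(199500, 201000))))
  res <- annotateAdjacentGenes(lnc, ref)
  ## overlapping genes at distance 0, ranked first
  expect_equal(res$distance[res$gene_id == "g1"], 0)
  expect_true(res$nearest[res$gene_id == "g1"])
  expect_true(res$nearest[res$gene_id == "g4"])   # also overlaps: tie at 0
  ## gap of 40 kb included, 150 kb-plus excluded (g3 is ~199 kb away)
  expect_equal(res$distance[res$gene_id == "g2"], 40000)
  expect_false("g3" %in% res$gene_id)
  ## empty result when nothing is in the window
  lonely <- txset(tx("L2", "chr2", "+", list(c(100, 500))))
  expect_equal(nrow(annotateAdjacentGenes(lonely, ref)), 0L)
})

test_that("TOM matches the brute-force oracle and its closed forms", {
  set.seed(8)
  for (i in 1:3) {
    m <- matrix(rnorm(10 * 12), nrow = 10,
                dimnames = list(paste0("n", 1:10), paste0("s", 1:12)))
    net <- buildTom(m)
    expect_equal(tomMatrix(net), oracleTom(m), tolerance = 1e-10)
  }
  ## identical profiles: all TOM = 1
  base <- rnorm(10)
  m2 <- rbind(a = base, b = base, c = base)
  colnames(m2) <- paste0("s", 1:10)
  expect_true(all(abs(tomMatrix(buildTom(m2)) - 1) < 1e-12))
  ## zero-variance rows are dropped and logged
  m3 <- rbind(a = rnorm(10), b = rep(3, 10), c = rnorm(10), d = rnorm(10))
  colnames(m3) <- paste0("s", 1:10)
  net3 <- buildTom(m3)
  expect_equal(net3@dropped, "b")
  expect_false("b" %in% tomNodes(net3))
  expect_error(buildTom(m3[, 1:3]), "4 samples")
})

test_that("co-expression partners are strictly above threshold, sorted", {
  base <- rnorm(12)
  m <- rbind(a = base, b = base + rnorm(12, 0, 0.01), c = rnorm(12),
             d = rnorm(12) * 0.1)
  colnames(m) <- paste0("s", 1:12)
  net <- buildTom(m)
  pa <- coexpressionPartners(net, "a")
  expect_true("b" %in% names(pa))
  expect_true(all(pa > 0.1))
  expect_equal(pa, sort(pa, decreasing = TRUE))
  expect_error(coexpressionPartners(net, "nope"), "unknown")
  ## weight exactly at threshold is excluded
  fake <- tomMatrix(net)
  expect_length(coexpressionPartners(net, "a", threshold = max(
    fake["a", setdiff(colnames(fake), "a")])), 0L)
})

test_that("GSEA finds extreme enrichment, is deterministic, and BH is
          monotone", {
  set.seed(5)
  ranking <- sort(abs(rnorm(100, 0, 0.2)), decreasing = TRUE)
  names(ranking) <- sprintf("g%03d", 1:100)
  sets <- list(top = names(ranking)[1:10],
               rand1 = sample(names(ranking), 20),
               rand2 = sample(names(ranking), 8),
               tiny = names(ranking)[1:3],          # below minSize: skipped
               rand3 = sample(names(ranking), 15))
  r1 <- gseaAnnotate(ranking, sets, nPerm = 1000, seed = 11)
  expect_false("tiny" %in% r1$term_id)
  expect_gt(r1$es[r1$term_id == "top"], 0.9)
  expect_lte(r1$p[r1$term_id == "top"], 0.01)
  ## deterministic for fixed seed
  r2 <- gseaAnnotate(ranking, sets, nPerm = 1000, seed = 11)
  expect_identical(r1, r2)
  ## BH adjusted values never fall below raw p and are monotone in p rank
  expect_true(all(r1$padj >= r1$p))
  expect_true(all(diff(r1$padj[order(r1$p)]) >= -1e-12))
  expect_error(gseaAnnotate(numeric(0), sets), "empty")
})

test_that("combineAnnotations applies union semantics and Venn counting", {
  universe <- paste0("L", 1:10)
  tissue <- data.frame(lncrna_id = c("L1", "L2"), tau = c(0.99, 0.99),
                       top_sample = "s1", top_tsi = 0.5, tie = FALSE,
                       specific = TRUE, tissue = "shoot",
                       stringsAsFactors = FALSE)
  adjacent <- data.frame(lncrna_id = c("L1", "L3"), gene_id = c("g1", "g2"),
                         distance = c(0, 100), nearest = TRUE,
                         stringsAsFactors = FALSE)
  coexp <- data.frame(lncrna_id = "L1", term_id = "GO:0000001",
                      stringsAsFactors = FALSE)
  out <- combineAnnotations(universe, tissue, adjacent, coexp)
  s <- out$summary
  expect_equal(s$n_annotated, 3L)                 # union of L1..L3
  expect_equal(s$percent_annotated, 30)
  expect_equal(unname(s$venn["all_three"]), 1L)   # L1 counted once
  expect_equal(unname(s$venn["tissue_only"]), 1L) # L2
  expect_equal(unname(s$venn["adjacent_only"]), 1L)
  ## all channels empty
  empty <- combineAnnotations(universe, NULL, NULL, NULL)
  expect_equal(empty$summary$percent_annotated, 0)
  expect_true(all(empty$summary$venn == 0))
})
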