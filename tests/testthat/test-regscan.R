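test_that("promoter extraction does the coordinate arithmetic", {
  contig <- randomDna(8000, 3)
  genome <- Biostrings::DNAStringSet(c(chr1 = contig))
  ## + strand transcript starting at 1-based 5001 (0-based TSS 5000):
  ## promoter = 1-based [2001, 5000], length 3000
  plus <- txset(tx("p", "chr1", "+", list(c(5001, 5400))))
  pr <- extractPromoter(plus["p"], genome)
  expect_equal(as.character(pr), substr(contig, 2001, 5000))
  expect_false(attr(pr, "truncated"))
  ## near the contig edge: truncated to [1, 1000]
  edge <- txset(tx("e", "chr1", "+", list(c(1001, 1300))))
  pe <- extractPromoter(edge["e"], genome)
  expect_equal(as.character(pe), substr(contig, 1, 1000))
  expect_true(attr(pe, "truncated"))
  ## zero room left
  zero <- txset(tx("z", "chr1", "+", list(c(1, 300))))
  expect_equal(length(extractPromoter(zero["z"], genome)), 0L)
  ## - strand: downstream window reverse-complemented
  minus <- txset(tx("m", "chr1", "-", list(c(2001, 2400))))
  pm <- extractPromoter(minus["m"], genome)
  expect_equal(as.character(pm), as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(contig, 2401, 5400)))))
})

test_that("degenerate PWMs have closed-form consensus scores and p-values", {
  bases <- c("A", "C", "G", "T")
  cons4 <- c("A", "C", "G", "T")
  m4 <- matrix(0, 4, 4, dimnames = list(bases, NULL))
  for (j in 1:4) m4[cons4[j], j] <- 1
  pwm4 <- newPWM(m4, id = "w4", pseudocount = 0)
  seqc <- paste0("TTTT", "ACGT", "TTTT")
  ## score at the consensus = 4 * log2(1/0.25) = 8 bits, p = 1/256: the scan
  ## threshold 1e-6 yields no hit
  hits <- scanPwm(seqc, pwm4, threshold = 1)
  consHit <- hits[hits$offset == 4 & hits$strand == "+", ]
  expect_equal(consHit$score, 8)
  expect_equal(consHit$p_value, 1 / 256)
  expect_equal(nrow(scanPwm(seqc, pwm4, threshold = 1e-6)), 0L)
  ## width 10: consensus p = 4^-10 < 1e-6 -> reported
  cons10 <- rep("A", 10)
  m10 <- matrix(0, 4, 10, dimnames = list(bases, NULL))
  m10["A", ] <- 1
  pwm10 <- newPWM(m10, id = "w10", pseudocount = 0)
  s10 <- paste0("CCCCC", paste(cons10, collapse = ""), "CCCCC")
  h10 <- scanPwm(s10, pwm10)
  expect_true(any(h10$offset == 5 & h10$strand == "+"))
  expect_equal(h10$p_value[h10$offset == 5 & h10$strand == "+"][1], 4^-10)
  ## all-N sequence scores 0 everywhere: no hits for a pseudocounted motif
  pwm10pc <- newPWM(m10, id = "w10pc", pseudocount = 0.01)
  expect_equal(nrow(scanPwm(strrep("N", 50), pwm10pc)), 0L)
  ## sequence shorter than the motif: empty result
  expect_equal(nrow(scanPwm("ACG", pwm10)), 0L)
})

test_that("exact p-values agree with exhaustive enumeration for w <= 8", {
  set.seed(17)
  bases <- c("A", "C", "G", "T")
  for (w in c(5L, 8L)) {
    raw <- matrix(rexp(4 * w), 4, w, dimnames = list(bases, NULL))
    pwm <- newPWM(raw, id = paste0("r", w))
    lods <- log2(pwm$matrix / pwm$background)
    ## enumerate all 4^w words and their real-valued scores
    grid <- as.matrix(expand.grid(rep(list(1:4), w)))
    scores <- numeric(nrow(grid))
    for (j in seq_len(w)) scores <- scores + lods[grid[, j], j]
    tab <- lncscape:::.pwmScoreTable(pwm)
    ## compare the DP tail with the enumeration tail on 50 sampled words
    idx <- sample(nrow(grid), 50)
    for (i in idx) {
      word <- paste(bases[grid[i, ]], collapse = "")
      h <- scanPwm(word, pwm, threshold = 1)
      pDp <- h$p_value[h$strand == "+" & h$offset == 0]
      pEnum <- mean(scores >= scores[i] - 1e-9) # uniform background
      expect_lt(abs(pDp - pEnum), 2e-3)
    }
  }
})

test_that("reverse-strand scanning equals forward scan of the reverse
          complement", {
  set.seed(19)
  raw <- matrix(rexp(4 * 6), 4, 6,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- newPWM(raw, id = "m")
  s <- randomDna(80, 23)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  fwd <- scanPwm(s, pwm, threshold = 1)
  back <- scanPwm(rc, pwm, threshold = 1)
  ## a - strand hit at offset o in s is a + strand hit at offset
  ## (L - w - o) in the reverse complement, with the same score
  L <- nchar(s); w <- pwm$width
  minus <- fwd[fwd$strand == "-", ]
  plus <- back[back$strand == "+", ]
  plusAt <- stats::setNames(plus$score, plus$offset)
  expect_equal(unname(plusAt[as.character(L - w - minus$offset)]),
               minus$score, tolerance = 1e-9)
})

test_that("MEME round trip preserves motif probabilities", {
  set.seed(29)
  raw <- matrix(rexp(4 * 7), 4, 7,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- newPWM(raw, id = "MX", pseudocount = 0.01)
  p <- tempfile(fileext = ".meme")
  writeMemeMotifs(list(pwm), p)
  back <- readMemeMotifs(p, pseudocount = 0)[[1]]
  expect_equal(back$id, "MX")
  expect_equal(unname(back$matrix), unname(pwm$matrix), tolerance = 1e-4)
})

test_that("reciprocal best hits: mutual-best definition and tie breaks", {
  hit <- function(q, s, e, b = 100)
    data.frame(query_id = q, subject_id = s, percent_identity = 50,
               alignment_length = 100, mismatches = 0, gap_opens = 0,
               q_start = 1, q_end = 100, s_start = 1, s_end = 100,
               e_value = e, bit_score = b, stringsAsFactors = FALSE)
  ab <- rbind(hit("a1", "b1", 1e-50), hit("a1", "b2", 1e-20),
              hit("a2", "b1", 1e-30))
  ba <- rbind(hit("b1", "a1", 1e-48), hit("b2", "a1", 1e-10))
  rb <- rbhOrthologs(ab, ba, secondary = FALSE)
  expect_equal(nrow(rb), 1L)
  expect_equal(rb$id_a, "a1")
  expect_equal(rb$id_b, "b1")
  expect_equal(rb$e_forward, 1e-50)
  expect_equal(rb$e_reverse, 1e-48)
  ## non-reciprocal best is not primary
  ba2 <- rbind(hit("b1", "a2", 1e-60), hit("b2", "a1", 1e-10))
  rb2 <- rbhOrthologs(ab, ba2, secondary = FALSE)
  expect_false(any(rb2$id_a == "a1" & rb2$id_b == "b1"))
  ## e-value tie broken by bit score, then subject id
  abTie <- rbind(hit("a1", "b2", 1e-50, b = 200), hit("a1", "b1", 1e-50, b = 100))
  baTie <- hit("b2", "a1", 1e-50)
  rbTie <- rbhOrthologs(abTie, baTie, secondary = FALSE)
  expect_equal(rbTie$id_b, "b2")
  ## empty input
  expect_equal(nrow(rbhOrthologs(ab[0, ], ba)), 0L)
})

test_that("rbh is symmetric in its two tables (primary tier)", {
  os <- makeOrthologScores(nA = 30, nB = 30, nOrthologs = 8, seed = 5)
  fwd <- rbhOrthologs(os$hitsAB, os$hitsBA, secondary = FALSE)
  rev_ <- rbhOrthologs(os$hitsBA, os$hitsAB, secondary = FALSE)
  expect_setequal(paste(fwd$id_a, fwd$id_b), paste(rev_$id_b, rev_$id_a))
})

test_that("secondary tier takes rank-2/3 hits below the e-value peak", {
  hit <- function(q, s, e)
    data.frame(query_id = q, subject_id = s, percent_identity = 50,
               alignment_length = 100, mismatches = 0, gap_opens = 0,
               q_start = 1, q_end = 100, s_start = 1, s_end = 100,
               e_value = e, bit_score = 100, stringsAsFactors = FALSE)
  ## many best hits near 1e-10 define the peak; one RBH query has a
  ## rank-2 hit far below it and a rank-3 hit above it
  set.seed(33)
  ab <- rbind(hit("a1", "b1", 1e-80), hit("a1", "b2", 1e-60),
              hit("a1", "b3", 1e-5),
              do.call(rbind, lapply(2:12, function(i)
                hit(paste0("a", i), paste0("b", i), 10^-runif(1, 9, 11)))))
  ba <- rbind(hit("b1", "a1", 1e-80),
              do.call(rbind, lapply(2:12, function(i)
                hit(paste0("b", i), paste0("a", i), 10^-runif(1, 9, 11)))))
  rb <- rbhOrthologs(ab, ba)
  sec <- rb[rb$tier == "secondary", ]
  expect_true(any(sec$id_a == "a1" & sec$id_b == "b2"))
  expect_false(any(sec$id_b == "b3"))
  expect_true(all(rb$rank_forward[rb$tier == "secondary"] %in% 2:3))
})
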