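test_that("chen dialect reader parses blocks and validates rows", {
  f <- tempfile(fileext = ".chen")
  writeLines(c(
    ">M0001_2.00\tlsy-2",
    "Pos\tA\tC\tG\tT",
    "1\t0.25\t0.25\t0.25\t0.25",
    "2\t0.25\t0.25\t0.25\t0.25",
    ">M0002_2.00\thsf-1",
    "Pos\tA\tC\tG\tT",
    "1\t0.97\t0.01\t0.01\t0.01",
    "2\t0.01\t0.97\t0.01\t0.01",
    "3\t0.01\t0.01\t0.97\t0.01",
    "4\t0.10\t0.20\t0.30\t0.40",
    "5\t0.40\t0.30\t0.20\t0.10",
    "6\t0.25\t0.25\t0.25\t0.25",
    "7\t0.01\t0.01\t0.01\t0.97"), f)
  pw <- readCisbpChen(f)
  expect_named(pw, c("M0001_2.00", "M0002_2.00"))
  expect_equal(motifWidth(pw[[1]]), 2L)
  expect_true(all(abs(probMatrix(pw[[1]]) - 0.25) < 1e-12))
  m2 <- probMatrix(pw[[2]])
  expect_equal(motifWidth(pw[[2]]), 7L)
  expect_equal(unname(m2[, 4]), c(0.10, 0.20, 0.30, 0.40))
  expect_equal(tfName(pw[[2]]), "hsf-1")
  expect_equal(consensusWord(pw[[2]]), "ACGTAAT")

  bad <- tempfile()
  writeLines(c(">Mx", "1\t0.5\t0.3\t0.1\t0.05"), bad)   # sums to 0.95
  expect_error(readCisbpChen(bad), "line 2")
  bad2 <- tempfile()
  writeLines(c(">Mx", "1\t0.5\tfoo\t0.25\t0.25"), bad2)
  expect_error(readCisbpChen(bad2), "non-numeric")
})

test_that("chen and MEME round trips reproduce matrices", {
  set.seed(21)
  pwms <- lapply(1:3, function(i) randomPwm(5 + i, sprintf("M%03d", i)))
  names(pwms) <- vapply(pwms, motifId, character(1))
  f <- tempfile()
  writeCisbpChen(pwms, f)
  back <- readCisbpChen(f)
  for (nm in names(pwms))
    expect_identical(probMatrix(back[[nm]]), probMatrix(pwms[[nm]]))
  f2 <- tempfile()
  writeMemeMotifs(pwms, f2, background = ZeroOrderBackground())
  back2 <- readMemeMotifs(f2)
  expect_named(back2$motifs, names(pwms))
  for (nm in names(pwms))
    expect_equal(probMatrix(back2$motifs[[nm]]), probMatrix(pwms[[nm]]),
                 tolerance = 1e-5)
})

test_that("zero-order background pools both strands with smoothing", {
  bg <- backgroundFromFasta(strrep("ACGT", 1000))
  expect_equal(unname(bgFreq(bg)), rep(0.25, 4), tolerance = 1e-3)
  bgA <- backgroundFromFasta(strrep("A", 2000))
  expect_equal(bgFreq(bgA)[["A"]], bgFreq(bgA)[["T"]])
  expect_equal(bgFreq(bgA)[["A"]], 0.5, tolerance = 1e-2)
  expect_true(all(bgFreq(bgA) > 0))     # smoothing keeps C/G positive
  ## 60%-AT genome matches direct both-strand counting
  set.seed(22)
  s <- randomSeq(50000, probs = c(0.3, 0.2, 0.2, 0.3))
  bg60 <- backgroundFromFasta(s)
  counts <- table(factor(strsplit(s, "")[[1]], levels = c("A","C","G","T")))
  pooled <- (counts + rev(counts) + 2) / (2 * sum(counts + 1))
  expect_equal(unname(bgFreq(bg60)), as.numeric(pooled), tolerance = 1e-9)
  expect_error(backgroundFromFasta("NNNNN"), "unambiguous")
})

test_that("log-odds scores follow the pseudocount formula", {
  u <- logOddsMatrix(PWMotif("u", matrix(0.25, 4, 3)),
                     ZeroOrderBackground())
  expect_true(all(abs(u@scores) < 1e-12))
  ## deterministic PWM, no pseudocount: 2 bits per position
  m <- matrix(0, 4, 3); m[cbind(c(1, 3, 4), 1:3)] <- 1
  sm <- logOddsMatrix(PWMotif("d", m), ZeroOrderBackground(),
                      pseudocount = 0)
  expect_equal(maxScore(sm), 6)
  ## arbitrary matrix against direct formula re-evaluation
  set.seed(23)
  pwm <- randomPwm(4)
  bg <- ZeroOrderBackground(c(A = 0.35, C = 0.15, G = 0.15, T = 0.35))
  sm2 <- logOddsMatrix(pwm, bg, pseudocount = 0.1)
  p <- probMatrix(pwm); f <- bgFreq(bg)
  for (b in 1:4) for (i in 1:4)
    expect_equal(sm2@scores[b, i],
                 log2(((p[b, i] + 0.1 * f[b]) / 1.1) / f[b]))
})

test_that("p-value table matches exhaustive enumeration and is monotone", {
  ## width-2 unique best word under uniform background: p(best) = 1/16
  m <- matrix(0.02, 4, 2); m[1, 1] <- 0.94; m[2, 2] <- 0.94
  sm <- logOddsMatrix(PWMotif("b", sweep(m, 2, colSums(m), "/")),
                      ZeroOrderBackground())
  best <- sum(apply(sm@intScores, 2, max))
  expect_equal(intScorePvalue(sm, best), 1 / 16)
  expect_equal(intScorePvalue(sm, 0L), 1)

  set.seed(24)
  for (bgf in list(c(0.25, 0.25, 0.25, 0.25), c(0.4, 0.1, 0.15, 0.35))) {
    bg <- ZeroOrderBackground(setNames(bgf, c("A", "C", "G", "T")))
    for (rep in 1:3) {
      sm <- logOddsMatrix(randomPwm(5), bg)
      en <- oracleWordDist(sm@intScores, bgFreq(bg))
      expect_equal(sum(en$prob), 1, tolerance = 1e-12)
      for (k in unique(c(0, round(quantile(en$intScore)), max(en$intScore)))) {
        expect_equal(intScorePvalue(sm, k), sum(en$prob[en$intScore >= k]),
                     tolerance = 1e-12)
      }
      expect_true(all(diff(sm@tail) <= 1e-15))
    }
  }
})

test_that("discretized word scores stay within w/2 bins of real scores", {
  set.seed(25)
  sm <- logOddsMatrix(randomPwm(6), ZeroOrderBackground())
  for (rep in 1:50) {
    word <- randomSeq(6)
    ws <- wordScore(sm, word)
    approx <- ws$intScore * sm@binSize + sm@offset
    expect_lt(abs(approx - ws$score), 6 / 2 * sm@binSize + 1e-9)
  }
})

test_that("scanner recovers planted exact matches at their exact starts", {
  set.seed(26)
  m <- matrix(0.02, 4, 8)
  for (i in 1:8) m[sample.int(4, 1), i] <- 0.94
  pwm <- PWMotif("M8", sweep(m, 2, colSums(m), "/"), "tf8")
  sm <- logOddsMatrix(pwm, ZeroOrderBackground())
  sv <- strsplit(randomSeq(6000), "")[[1]]
  pos <- sort(sample(seq(1, 5900, by = 40), 10))
  for (p in pos) sv[p:(p + 7)] <- strsplit(consensusWord(pwm), "")[[1]]
  genome <- DNAStringSet(paste(sv, collapse = "")); names(genome) <- "chrI"
  hits <- scanGenome(genome, sm, pThreshold = 1e-4)
  expect_true(all(pos %in% start(hits)))
  plantHits <- hits[start(hits) %in% pos]
  expect_true(all(plantHits$pvalue <= 1e-4))
  expect_equal(unique(plantHits$name), "M8")
  expect_equal(unique(width(hits)), 8L)
})

test_that("scanning the reverse-complemented genome mirrors hits", {
  set.seed(27)
  sm <- logOddsMatrix(randomPwm(6, concentration = 0.3),
                      ZeroOrderBackground())
  for (rep in 1:10) {
    g <- DNAStringSet(randomSeq(800)); names(g) <- "chrI"
    rc <- reverseComplement(g); names(rc) <- "chrI"
    h <- scanGenome(g, sm, pThreshold = 5e-3)
    hrc <- scanGenome(rc, sm, pThreshold = 5e-3)
    expect_equal(sort(start(h)), sort(801L - end(hrc)))
    expect_equal(sum(strand(h) == "+"), sum(strand(hrc) == "-"))
    expect_equal(sort(unname(h$score)), sort(unname(hrc$score)),
                 tolerance = 1e-12)
  }
})

test_that("scan is threshold-monotone, order-invariant and skips N windows", {
  set.seed(28)
  sm <- logOddsMatrix(randomPwm(6, concentration = 0.3),
                      ZeroOrderBackground())
  g <- DNAStringSet(c(chrI = randomSeq(2000), chrII = randomSeq(1500)))
  loose <- scanGenome(g, sm, pThreshold = 1e-2)
  strict <- scanGenome(g, sm, pThreshold = 1e-3)
  key <- function(h) paste(seqnames(h), start(h), strand(h))
  expect_true(all(key(strict) %in% key(loose)))
  g2 <- g[c(2, 1)]
  expect_setequal(key(scanGenome(g2, sm, pThreshold = 1e-2)), key(loose))
  ## N windows are skipped entirely
  sv <- strsplit(as.character(g[["chrI"]]), "")[[1]]
  nPos <- 1000:1005
  sv[nPos] <- "N"
  gN <- DNAStringSet(paste(sv, collapse = "")); names(gN) <- "chrI"
  hN <- scanGenome(gN, sm, pThreshold = 1e-2)
  expect_false(any(start(hN) > 995 & start(hN) <= 1005))
  ## short chromosome: notice, not error
  gS <- DNAStringSet(c(chrI = randomSeq(500), tiny = "ACG"))
  expect_message(scanGenome(gS, sm, pThreshold = 1e-2), "skipped")
})

test_that("max-strand keeps the better-scoring strand with + on ties", {
  ## palindromic consensus scores identically on both strands
  m <- matrix(0.01, 4, 4)
  m[cbind(c(1, 2, 3, 4), 1:4)] <- 0.97   # ACGT, its own reverse complement
  pwm <- PWMotif("pal", sweep(m, 2, colSums(m), "/"))
  sm <- logOddsMatrix(pwm, ZeroOrderBackground())
  g <- DNAStringSet(c(chrI = paste0(strrep("GG", 10), "ACGT",
                                    strrep("TT", 10))))
  hits <- scanGenome(g, sm, pThreshold = 5e-3, maxStrand = TRUE)
  at <- hits[start(hits) == 21]
  expect_equal(length(at), 1L)
  expect_equal(as.character(strand(at)), "+")
  both <- scanGenome(g, sm, pThreshold = 5e-3, maxStrand = FALSE)
  expect_equal(length(both[start(both) == 21]), 2L)
})

test_that("hit BED round trip preserves all hit fields", {
  set.seed(29)
  sm <- logOddsMatrix(randomPwm(6, concentration = 0.3),
                      ZeroOrderBackground())
  g <- DNAStringSet(c(chrI = randomSeq(3000)))
  hits <- scanGenome(g, sm, pThreshold = 1e-2)
  f <- tempfile(fileext = ".bed")
  writeHitsBed(hits, f)
  back <- readHitsBed(f, seqlen = genomeSeqlengths(g))
  expect_equal(length(back), length(hits))
  expect_equal(start(back), start(hits))
  expect_equal(as.character(strand(back)), as.character(strand(hits)))
  expect_equal(back$pvalue, hits$pvalue, tolerance = 1e-5)
})
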