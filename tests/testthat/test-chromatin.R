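test_that("summit regions are 101 bp, clipped and merged across stages", {
  sl <- c(chrI = 10000L)
  s1 <- GRanges("chrI", IRanges(101, 101))      # BED summit at 100
  reg <- buildSummitRegions(s1, seqlen = sl)
  expect_equal(c(start(preMergeRegions(reg)), end(preMergeRegions(reg))),
               c(51L, 151L))
  expect_equal(width(preMergeRegions(reg)), 101L)
  ## clipped near the chromosome start: BED summit 20 -> [0, 71)
  s2 <- GRanges("chrI", IRanges(21, 21))
  reg2 <- buildSummitRegions(s2, seqlen = sl)
  expect_equal(c(start(preMergeRegions(reg2)), end(preMergeRegions(reg2))),
               c(1L, 71L))
  ## two stages at 100 and 140 merge into one [50, 191) region
  s3 <- GRanges("chrI", IRanges(141, 141))
  reg3 <- buildSummitRegions(list(s1, s3), seqlen = sl)
  m <- mergedRegions(reg3)
  expect_equal(length(m), 1L)
  expect_equal(c(start(m), end(m)), c(51L, 191L))
  ## off-chromosome summit rejected with a notice
  s4 <- GRanges("chrI", IRanges(20000, 20000))
  expect_message(buildSummitRegions(list(s1, s4), seqlen = sl), "rejected")
  expect_error(buildSummitRegions(GRanges("chrI", IRanges(5, 10)),
                                  seqlen = sl), "single-base")
})

test_that("accessible fractions count containment and gate strictly", {
  sl <- c(chrI = 100000L)
  tes <- GRanges("chrI", IRanges(10000, 11999), seqlengths = sl)
  tes$te_type <- "TcA"; tes$te_family <- "f"; tes$repeat_class <- "DNA"
  ## 4 hits in TEs, 4 outside; ATAC covers the 4 in-TE hits + 2 outside
  inTe <- GRanges("chrI", IRanges(seq(10100, 11600, by = 500), width = 10))
  out <- GRanges("chrI", IRanges(seq(30000, 60000, by = 10000), width = 10))
  hits <- c(inTe, out)
  hits$name <- "M1"
  summits <- GRanges("chrI", IRanges(c(start(inTe) + 5, 30005, 40005),
                                     width = 1), seqlengths = sl)
  atac <- buildSummitRegions(summits, seqlen = sl)
  fr <- accessibleMotifFractions(hits, atac, tes, minSites = 3, minPct = 10)
  expect_equal(fr$n_accessible, 6L)
  expect_equal(fr$n_accessible_te, 4L)
  expect_equal(fr$percent, 100 * 4 / 6)
  expect_true(fr$passes)
  ## denominator floor is strict: exactly minSites fails
  fr2 <- accessibleMotifFractions(hits, atac, tes, minSites = 6, minPct = 10)
  expect_false(fr2$pass_floor)
  ## all in-TE hits accessible, no others -> 100%
  atac2 <- buildSummitRegions(GRanges("chrI", IRanges(start(inTe) + 5,
                                                      width = 1)),
                              seqlen = sl)
  fr3 <- accessibleMotifFractions(hits, atac2, tes, minSites = 1, minPct = 10)
  expect_equal(fr3$percent, 100)
})

test_that("bound fractions count regions once and respect floors", {
  sl <- c(chrI = 1000000L)
  tes <- GRanges("chrI", IRanges(1000, 81000), seqlengths = sl)
  tes$te_type <- "TcA"; tes$te_family <- "f"; tes$repeat_class <- "DNA"
  ## 1000 bound regions; 80 contain a TE-contained motif, 120 a non-TE one
  summitPos <- 2000L + 998L * (0:999)
  chip <- buildSummitRegions(GRanges("chrI", IRanges(summitPos, width = 1)),
                             label = "M1", seqlen = sl)
  hits <- GRanges("chrI", IRanges(c(summitPos[1:80], summitPos[101:220]) + 5,
                                  width = 10), seqlengths = sl)
  hits$name <- "M1"
  fr <- boundMotifFractions(hits, list(M1 = chip), tes,
                            minRegions = 500, minPct = 5)
  expect_equal(fr$n_bound_regions, 1000L)
  expect_equal(fr$n_bound_with_motif, 200L)
  expect_equal(fr$n_bound_te, 80L)
  expect_equal(fr$percent, 40)
  expect_true(fr$passes)
  ## 499 bound regions -> gated out regardless of percent
  chipSmall <- buildSummitRegions(
    GRanges("chrI", IRanges(summitPos[1:499], width = 1)), seqlen = sl)
  fr2 <- boundMotifFractions(hits, list(M1 = chipSmall), tes,
                             minRegions = 500, minPct = 5)
  expect_false(fr2$pass_floor)
  ## a region with several hits counts once
  multi <- c(hits, GRanges("chrI", IRanges(summitPos[1] + 20, width = 10),
                           name = "M1"))
  fr3 <- boundMotifFractions(multi, list(M1 = chip), tes,
                             minRegions = 500, minPct = 5)
  expect_equal(fr3$n_bound_with_motif, 200L)
})

test_that("top TE contributors rank by count with lexicographic ties", {
  df <- data.frame(name = "M1",
                   te_type = rep(c("A", "B", "C"), c(5, 3, 1)))
  top <- topTeContributors(df, k = 2)
  expect_equal(top$te_type, c("A", "B"))
  expect_equal(top$count, c(5L, 3L))
  tie <- data.frame(name = "M1", te_type = rep(c("B", "A"), c(3, 3)))
  expect_equal(topTeContributors(tie, k = 1)$te_type, "A")
  ## agrees with a full-sort oracle on random counts
  set.seed(41)
  rnd <- data.frame(name = sample(c("M1", "M2"), 300, replace = TRUE),
                    te_type = sample(LETTERS[1:6], 300, replace = TRUE))
  top5 <- topTeContributors(rnd, k = 5)
  for (m in c("M1", "M2")) {
    tab <- table(rnd$te_type[rnd$name == m])
    ord <- names(tab)[order(-as.integer(tab), names(tab))]
    expect_equal(top5$te_type[top5$name == m], head(ord, 5))
  }
})

test_that("Fisher's exact test matches enumeration at fixed margins", {
  res <- teFisherTest(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(res$p, 34 / 70, tolerance = 1e-10)
  expect_false(res$degenerate)
  deg <- teFisherTest(matrix(c(0, 5, 0, 7), 2, byrow = TRUE))
  expect_equal(deg$p, 1)
  expect_true(deg$degenerate)
  ## all 2x2 tables with N <= 40 sampled densely against the oracle
  set.seed(42)
  for (rep in 1:200) {
    N <- sample(4:40, 1)
    a <- sample.int(N, 1) - 1L
    b <- sample.int(N - a, 1) - 1L
    cc <- sample.int(max(N - a - b, 1), 1) - 1L
    d <- N - a - b - cc
    tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(teFisherTest(tab)$p, oracleFisherTwoSided(tab),
                 tolerance = 1e-10)
  }
})

test_that("accessibility association builds the documented 2x2 table", {
  sl <- c(chrI = 100000L)
  summitPos <- seq(1000, 97000, by = 2000)
  chip <- buildSummitRegions(GRanges("chrI", IRanges(summitPos, width = 1)),
                             seqlen = sl)
  ## TE-motif hits inside the first 20 bound regions; ATAC over regions
  ## 1..10 and 25..40
  teHits <- GRanges("chrI", IRanges(summitPos[1:20] + 3, width = 10),
                    seqlengths = sl)
  atac <- buildSummitRegions(
    GRanges("chrI", IRanges(summitPos[c(1:10, 25:40)], width = 1)),
    seqlen = sl)
  res <- accessibilityFisher(chip, atac, teHits)
  expect_equal(unname(res$table[1, ]), c(10L, 10L))
  expect_equal(unname(res$table[2, ]), c(16L, 13L))
  expect_equal(res$p, oracleFisherTwoSided(res$table), tolerance = 1e-10)
})
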