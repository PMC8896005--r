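test_that("coverage percentages and fold changes follow their definitions", {
  expect_equal(round(percentTeCoverage(9.18e6, 100.29e6), 1), 9.2)
  fc <- foldVsNonTe(53.1, 33.3)
  expect_equal(round(fc$display, 1), 1.6)
  expect_equal(fc$direction, "enrichment")
  dep <- foldVsNonTe(1.0, 27.8)
  expect_equal(round(dep$display, 1), 27.8)
  expect_equal(dep$direction, "depletion")
  expect_equal(foldVsNonTe(0, 10)$direction, "infinite_depletion")
  ## zero-length class flagged, not divided
  part <- data.frame(class = c("empty", "whole_genome"),
                     class_bp = c(0, 1000), te_bp = c(0, 100))
  ct <- coverageTable(part)
  expect_true(ct$flag_zero_class[1])
  expect_true(is.na(ct$percent_te[1]))
})

test_that("coverage table reproduces share-based folds from a partition", {
  ## genome 1000 kb, TEs 100 kb; a class with 53.1% of TE space and 33.3%
  ## of non-TE space must come out 1.6-fold enriched
  teBp <- 1e5; genomeBp <- 1e6
  clTe <- 0.531 * teBp; clNon <- 0.333 * (genomeBp - teBp)
  part <- data.frame(class = c("introns", "whole_genome"),
                     class_bp = c(clTe + clNon, genomeBp),
                     te_bp = c(clTe, teBp))
  ct <- coverageTable(part)
  row <- ct[ct$class == "introns", ]
  expect_equal(round(row$share_of_te, 1), 53.1)
  expect_equal(round(row$share_of_nonte, 1), 33.3)
  expect_equal(round(row$fold_display, 1), 1.6)
})

test_that("motif-TE enrichment computes fold and exact binomial tails", {
  sl <- c(chrI = 100000L)
  ## TE type covering exactly 1% of the genome
  tes <- GRanges("chrI", IRanges(seq(1000, 9800, by = 4400), width = 200L),
                 seqlengths = sl)
  tes$te_type <- "TcA"; tes$te_family <- "f"; tes$repeat_class <- "DNA"
  stopifnot(sum(width(tes)) == 600)
  tes <- c(tes, GRanges("chrI", IRanges(50000, 50399), seqlengths = sl))
  tes$te_type[4] <- "TcA"; tes$te_family[4] <- "f"; tes$repeat_class[4] <- "DNA"
  ## 10 hits, 2 inside (20%) -> fold = 0.2 / 0.01 = 20
  inside <- c(1005, 50010)
  outside <- seq(20000, 27000, by = 1000)
  hits <- GRanges("chrI", IRanges(c(inside, outside), width = 10L),
                  seqlengths = sl)
  hits$name <- "M1"
  rec <- motifTeEnrichment(hits, tes, sl)
  expect_equal(rec$n_total, 10L)
  expect_equal(rec$n_in, 2L)
  expect_equal(rec$te_bp, 1000)
  expect_equal(rec$fold, 20)
  expect_equal(rec$p, oracleBinomTail(2, 10, 0.01), tolerance = 1e-12)
  ## no hits inside -> one-sided p = 1
  hitsOut <- hits[3:10]
  recOut <- motifTeEnrichment(hitsOut, tes, sl)
  expect_equal(recOut$n_in, 0L)
  expect_equal(recOut$p, 1)
})

test_that("binomial tail equals direct pmf summation across sizes", {
  ## the printed example: n=10, k=5, p0=0.1
  expect_equal(pbinom(4, 10, 0.1, lower.tail = FALSE),
               oracleBinomTail(5, 10, 0.1), tolerance = 1e-12)
  expect_equal(round(oracleBinomTail(5, 10, 0.1), 5), 0.00163)
  set.seed(31)
  for (n in c(10, 100, 1000, 10000)) {
    p <- runif(1, 0.001, 0.2)
    k <- rbinom(1, n, p) + sample(0:3, 1)
    expect_equal(pbinom(k - 1, n, p, lower.tail = FALSE),
                 oracleBinomTail(k, n, p), tolerance = 1e-12)
  }
})

test_that("fold is invariant under uniform genome scaling", {
  sl <- c(chrI = 50000L)
  tes <- GRanges("chrI", IRanges(c(5000, 20000), width = 500L),
                 seqlengths = sl)
  tes$te_type <- "TcA"; tes$te_family <- "f"; tes$repeat_class <- "DNA"
  hits <- GRanges("chrI", IRanges(c(5100, 5300, 30000, 40000), width = 10L),
                  seqlengths = sl)
  hits$name <- "M1"
  rec1 <- motifTeEnrichment(hits, tes, sl)
  double <- function(gr, sl2) {
    g <- GRanges(seqnames(gr), IRanges(2L * start(gr), 2L * end(gr)),
                 seqlengths = sl2)
    mcols(g) <- mcols(gr)
    g
  }
  sl2 <- c(chrI = 100000L)
  tes2 <- double(tes, sl2)
  ## doubling coordinates doubles te widths and genome alike
  rec2 <- motifTeEnrichment(double(hits, sl2), tes2, sl2)
  expect_equal(rec2$fold, rec1$fold, tolerance = 0.01)
})

test_that("the gate cascade applies strict thresholds", {
  rec <- data.frame(name = "M1", te_type = c("a", "b", "c", "d", "e"),
                    te_bp = c(30000, 19000, 30000, 30000, 20000),
                    fold = c(25, 25, 20, 25, 25),
                    p = c(1e-15, 1e-15, 1e-15, 1e-12, 1e-15))
  keep <- filterEnriched(rec)
  expect_equal(keep$te_type, c("a", "e")[1])   # only the first passes all
  expect_equal(nrow(filterEnriched(rec, minTeBp = 20000)), 1L)  # 20000 not > 20000
  flags <- filterEnriched(rec, returnAll = TRUE)
  expect_equal(flags$passes_filters, c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("motif percentage inside chosen TE types is count arithmetic", {
  rec <- data.frame(name = "M1", te_type = c("a", "b", "c"),
                    n_total = 200L, n_in = c(30L, 10L, 0L))
  expect_equal(motifPercentInTe(rec, "M1", c("a", "b")), 20)
  expect_equal(motifPercentInTe(rec, "M1"), 20)
  expect_equal(motifPercentInTe(rec, "M1", character(0)), 0)
  expect_equal(motifPercentInTe(rec, "M1", "a"), 15)
  bad <- data.frame(name = "M2", te_type = "a", n_total = 0L, n_in = 0L)
  expect_error(motifPercentInTe(bad, "M2"), "no genomic instances")
})

test_that("promoter gene counting counts genes, not hits", {
  sl <- c(chrI = 50000L)
  prom <- GRanges("chrI", IRanges(c(1000, 1500, 30000), width = 2500),
                  seqlengths = sl)
  prom$gene_id <- c("g1", "g2", "g3")
  hits <- GRanges("chrI", IRanges(c(2000, 31000), width = 10),
                  seqlengths = sl)
  hits$name <- c("M1", "M1")
  hits$te_type <- "TcA"; hits$te_family <- "f"
  res <- genesWithTeMotifs(prom, hits)
  ## the first hit sits in both overlapping windows
  expect_setequal(res$perMotif$M1, c("g1", "g2", "g3"))
  expect_equal(res$unionGenes, c("g1", "g2", "g3"))
  ## union is bounded by the sum of per-motif counts
  expect_lte(length(res$unionGenes), sum(lengths(res$perMotif)))
  ## boundary: hit must lie fully within the window
  edge <- GRanges("chrI", IRanges(32495, 32504), seqlengths = sl) # crosses end
  edge$name <- "M2"; edge$te_type <- "TcA"; edge$te_family <- "f"
  res2 <- genesWithTeMotifs(prom, edge)
  expect_false("M2" %in% names(res2$perMotif))
})

test_that("random planted layout matches a per-base assignment oracle", {
  set.seed(32)
  sl <- c(chrI = 60000L)
  ps <- sample.int(55000, 30)
  prom <- GRanges("chrI", IRanges(ps, width = 2500), seqlengths = sl)
  prom$gene_id <- sprintf("g%02d", 1:30)
  hs <- sample.int(59000, 120)
  hits <- GRanges("chrI", IRanges(hs, width = 10), seqlengths = sl)
  hits$name <- sample(c("M1", "M2"), 120, replace = TRUE)
  hits$te_type <- "TcA"; hits$te_family <- "f"
  res <- genesWithTeMotifs(prom, hits)
  for (m in c("M1", "M2")) {
    expected <- character(0)
    for (g in seq_len(30)) {
      win <- c(ps[g], ps[g] + 2499)
      mine <- hs[hits$name == m]
      if (any(mine >= win[1] & mine + 9 <= win[2]))
        expected <- c(expected, prom$gene_id[g])
    }
    expect_setequal(res$perMotif[[m]], expected)
  }
})
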