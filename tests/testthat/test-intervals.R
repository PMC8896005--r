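test_that("merge unions overlapping and book-ended intervals", {
  expect_length(mergeIntervals(GRanges()), 0L)
  gr <- GRanges("chrI", IRanges(c(1, 11), c(10, 20)))
  m <- mergeIntervals(gr)
  expect_equal(length(m), 1L)
  expect_equal(start(m), 1L)
  expect_equal(end(m), 20L)
  ## idempotent and order-independent
  set.seed(42)
  for (rep in 1:5) {
    st <- sample.int(9900, 200)
    gr <- GRanges("chrI", IRanges(st, st + sample.int(300, 200)))
    m <- mergeIntervals(gr)
    expect_identical(granges(m), granges(mergeIntervals(m)))
    expect_identical(granges(m),
                     granges(mergeIntervals(gr[sample(200)])))
    ## covered bases match the per-base oracle
    cov <- oracleBitmap(start(gr), end(gr), 10300)
    expect_equal(sum(width(m)), sum(cov))
    ## no two members overlap or abut
    if (length(m) > 1L)
      expect_true(all(start(m)[-1] - end(m)[-length(m)] > 1L))
  }
})

test_that("malformed BED intervals are rejected with the offender named", {
  f <- tempfile(fileext = ".bed")
  writeLines(c("chrI\t10\t20\tx\t0\t+", "chrI\t30\t30\ty\t0\t-"), f)
  expect_error(readBed(f), "line 2")
})

test_that("containment keeps exactly the hits fully inside a TE", {
  tes <- GRanges("chrI", IRanges(c(1, 100), c(50, 200)))
  tes$te_type <- c("TcA", "HelA")
  tes$te_family <- c("Tc1/mariner", "Helitron")
  hits <- GRanges("chrI", IRanges(c(6, 46, 150), width = 8))
  hits$name <- "M1"
  out <- containedHits(hits, tes)
  expect_equal(start(out), c(6L, 150L))       # 46-53 straddles the boundary
  expect_equal(out$te_type, c("TcA", "HelA"))
  ## containment implies overlap
  expect_true(all(overlapsAny(out, tes, ignore.strand = TRUE)))
})

test_that("containment of planted hits recovers the planted inside-list", {
  set.seed(7)
  len <- 50000L
  teSt <- seq(1000L, 48000L, by = 500L)
  tes <- GRanges("chrI", IRanges(teSt, width = 200L))
  tes$te_type <- "TcA"; tes$te_family <- "Tc1/mariner"
  inside <- vapply(sample(teSt, 250, replace = TRUE),
                   function(s) s + sample.int(190, 1), integer(1))
  outside <- vapply(1:250, function(i) {
    repeat {
      p <- sample.int(len - 10L, 1)
      hitsTe <- any(p <= teSt + 199L & p + 9L >= teSt)
      if (!hitsTe) return(p)
    }
  }, integer(1))
  hits <- GRanges("chrI", IRanges(c(inside, outside), width = 10L))
  hits$name <- "M1"
  hits$planted_inside <- rep(c(TRUE, FALSE), each = 250)
  out <- containedHits(hits, tes)
  expect_setequal(start(out), inside)
  expect_true(all(out$planted_inside))
})

test_that("overlapping TE records resolve to longest cover, then name", {
  tes <- GRanges("chrI", IRanges(c(1, 1, 40), c(100, 60, 139)))
  tes$te_type <- c("Bbb", "Aaa", "Aaa")
  tes$te_family <- "f"
  hit <- GRanges("chrI", IRanges(50, 59)); hit$name <- "M1"
  out <- containedHits(hit, tes)
  ## two covering records tie at width 100; lexicographic type breaks it
  expect_equal(out$te_type, "Aaa")
  expect_true(out$te_ambiguous)
  ## equal widths: lexicographic type wins
  tes2 <- GRanges("chrI", IRanges(c(1, 1), c(100, 100)))
  tes2$te_type <- c("Zz", "Aa"); tes2$te_family <- "f"
  out2 <- containedHits(hit, tes2)
  expect_equal(out2$te_type, "Aa")
})

test_that("promoter windows reflect strand, clip at ends, respect length", {
  sl <- c(chrI = 100000L)
  genes <- GRanges("chrI", IRanges(c(1001, 1001), c(2000, 2000)),
                   strand = c("+", "-"), seqlengths = sl)
  genes$gene_id <- c("g1", "g2")
  prom <- promoterRegions(GeneModels(genes = genes), upstreamBp = 2500)
  plus <- prom[prom$gene_id == "g1"]
  minus <- prom[prom$gene_id == "g2"]
  expect_equal(c(start(plus), end(plus)), c(1L, 1000L))      # clipped
  expect_equal(c(start(minus), end(minus)), c(2001L, 4500L)) # reflected
  expect_true(all(width(prom) <= 2500))
  expect_true(all(end(prom) <= sl & start(prom) >= 1L))
  unstranded <- GRanges("chrI", IRanges(5000, 6000), strand = "*",
                        seqlengths = sl)
  unstranded$gene_id <- "g3"
  expect_error(promoterRegions(GeneModels(genes = unstranded)), "stranded")
})

test_that("exclusive promoters subtract features, matching a bitmap oracle", {
  set.seed(11)
  sl <- c(chrI = 60000L)
  gs <- seq(5000L, 55000L, by = 5000L)
  strandv <- sample(c("+", "-"), length(gs), replace = TRUE)
  genes <- GRanges("chrI", IRanges(gs, gs + 1999L), strand = strandv,
                   seqlengths = sl)
  genes$gene_id <- sprintf("g%02d", seq_along(gs))
  exons <- GRanges("chrI", IRanges(gs + 100L, gs + 700L), strand = strandv,
                   seqlengths = sl)
  exons$gene_id <- genes$gene_id
  gm <- GeneModels(genes = genes, exons = exons)
  prom <- promoterRegions(gm, upstreamBp = 2500, exclusive = TRUE)
  ## oracle: per-base window minus feature bases
  featCov <- oracleBitmap(start(exons), end(exons), sl[[1]])
  intrCov <- oracleBitmap(start(geneIntrons(gm)), end(geneIntrons(gm)),
                          sl[[1]])
  for (i in seq_along(genes)) {
    win <- if (strandv[i] == "+") (gs[i] - 2500):(gs[i] - 1)
           else (gs[i] + 2000):(gs[i] + 4499)
    win <- win[win >= 1 & win <= sl[[1]]]
    expWidth <- sum(!featCov[win] & !intrCov[win])
    mine <- prom[prom$gene_id == genes$gene_id[i]]
    expect_equal(sum(width(mine)), expWidth)
  }
})

test_that("operon genes yield one operon promoter in the exclusive variant", {
  sl <- c(chrI = 50000L)
  genes <- GRanges("chrI", IRanges(c(10000, 12000, 30000), width = 1000),
                   strand = "+", seqlengths = sl)
  genes$gene_id <- c("g1", "g2", "g3")
  genes$operon_id <- c("op1", "op1", NA)
  operons <- GRanges("chrI", IRanges(10000, 12999), strand = "+",
                     seqlengths = sl)
  operons$operon_id <- "op1"
  gm <- GeneModels(genes = genes, operons = operons)
  promEx <- promoterRegions(gm, exclusive = TRUE, useOperons = TRUE)
  expect_setequal(promEx$gene_id, c("op1", "g3"))
  expect_equal(start(promEx[promEx$gene_id == "op1"]), 7500L)
  ## inclusive variant: every gene gets its own window
  promInc <- promoterRegions(gm, exclusive = FALSE)
  expect_setequal(promInc$gene_id, c("g1", "g2", "g3"))
})

test_that("feature partition matches a per-base class/TE bitmap oracle", {
  set.seed(13)
  sl <- c(chrI = 40000L, chrII = 30000L)
  mkGenes <- function() {
    gs <- c(seq(6000, 36000, by = 6000), seq(5000, 25000, by = 7000))
    ch <- rep(c("chrI", "chrII"), c(6, 3))
    std <- sample(c("+", "-"), 9, replace = TRUE)
    genes <- GRanges(ch, IRanges(gs, gs + 1499L), strand = std,
                     seqlengths = sl)
    genes$gene_id <- sprintf("g%02d", 1:9)
    exons <- GRanges(ch, IRanges(gs + 200L, gs + 600L), strand = std,
                     seqlengths = sl)
    exons$gene_id <- genes$gene_id
    utr5 <- GRanges(ch, IRanges(gs, gs + 99L), strand = std,
                    seqlengths = sl)
    utr5$gene_id <- genes$gene_id
    GeneModels(genes = genes, exons = exons, utr5 = utr5)
  }
  gm <- mkGenes()
  teSt <- c(sample.int(39000, 25), sample.int(29000, 15))
  tes <- GRanges(rep(c("chrI", "chrII"), c(25, 15)),
                 IRanges(teSt, width = 400L), seqlengths = sl)
  tes$te_type <- "TcA"; tes$te_family <- "f"; tes$repeat_class <- "DNA"
  part <- featurePartition(sl, gm, tes)

  teCov <- list(chrI = oracleBitmap(start(tes)[1:25], pmin(end(tes)[1:25], sl[1]), sl[[1]]),
                chrII = oracleBitmap(start(tes)[26:40], pmin(end(tes)[26:40], sl[2]), sl[[2]]))
  classCov <- function(gr) {
    lapply(names(sl), function(ch) {
      g <- gr[as.character(seqnames(gr)) == ch]
      if (length(g) == 0L) logical(sl[[ch]])
      else oracleBitmap(start(g), end(g), sl[[ch]])
    })
  }
  checkRow <- function(class, gr) {
    cc <- classCov(gr)
    expect_equal(part$class_bp[part$class == class],
                 sum(vapply(cc, sum, integer(1))))
    expect_equal(part$te_bp[part$class == class],
                 sum(mapply(function(a, b) sum(a & b), cc, teCov)))
  }
  checkRow("coding_exons", codingExons(gm))
  checkRow("utr5", fivePrimeUTRs(gm))
  checkRow("introns", geneIntrons(gm))
  prom <- promoterRegions(gm, exclusive = TRUE, useOperons = TRUE)
  checkRow("promoters", prom[prom$unit == "gene"])
  ## distal intergenic: complement of everything else
  allCov <- mapply(function(...) Reduce(`|`, list(...)),
                   classCov(codingExons(gm)), classCov(fivePrimeUTRs(gm)),
                   classCov(threePrimeUTRs(gm)), classCov(geneIntrons(gm)),
                   classCov(prom), SIMPLIFY = FALSE)
  expect_equal(part$class_bp[part$class == "distal_intergenic"],
               sum(vapply(allCov, function(x) sum(!x), integer(1))))
  ## for every class: TE bp never exceeds class bp
  expect_true(all(part$te_bp <= part$class_bp))
  expect_equal(part$class_bp[part$class == "whole_genome"], sum(sl))
})

test_that("TE fully inside an intron is booked to introns, not intergenic", {
  sl <- c(chrI = 30000L)
  genes <- GRanges("chrI", IRanges(10000, 14999), strand = "+",
                   seqlengths = sl)
  genes$gene_id <- "g1"
  exons <- GRanges("chrI", IRanges(c(10000, 14000), c(11000, 14999)),
                   strand = "+", seqlengths = sl)
  exons$gene_id <- "g1"
  gm <- GeneModels(genes = genes, exons = exons)  # intron 11001-13999
  tes <- GRanges("chrI", IRanges(12000, 12999), seqlengths = sl)
  tes$te_type <- "TcA"; tes$te_family <- "f"; tes$repeat_class <- "DNA"
  part <- featurePartition(sl, gm, tes)
  expect_equal(part$te_bp[part$class == "introns"], 1000)
  expect_equal(part$te_bp[part$class == "distal_intergenic"], 0)
  expect_equal(part$te_bp[part$class == "coding_exons"], 0)
})
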