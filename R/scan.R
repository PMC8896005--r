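#' Estimate a zero-order background from genome sequence
#'
#' Counts mononucleotides over both strands (each base pooled with its
#' complement, so freq(A) = freq(T) and freq(C) = freq(G)), ignoring
#' ambiguous bases, with add-one smoothing so no frequency is zero.
#'
#' @param genome DNAStringSet (or a single character sequence)
#' @param pool pool counts with the reverse-complement strand (default
#'   TRUE, matching the usual background-estimation convention); set FALSE
#'   to use the forward strand only
#' @return a [ZeroOrderBackground-class]
#' @export
backgroundFromFasta <- function(genome, pool = TRUE) {
  if (is.character(genome)) genome <- DNAStringSet(genome)
  counts <- colSums(letterFrequency(genome, DNA_BASES))
  if (sum(counts) == 0) .stopf("no unambiguous bases in input")
  counts <- counts + 1  # add-one smoothing
  if (pool) {
    counts <- (counts + counts[c(4, 3, 2, 1)]) / 2
  }
  ZeroOrderBackground(counts / sum(counts))
}

#' Build a log-odds scoring matrix with its exact p-value table
#'
#' Transforms a probability matrix into per-position log2-odds scores
#' against a zero-order background,
#' `score(i, b) = log2(((p_ib + c * bg_b) / (1 + c)) / bg_b)` with
#' pseudocount `c` distributed proportionally to the background. The exact
#' distribution of the total score over random background words is then
#' computed by dynamic programming on a discretized copy of the matrix
#' (per-position scores shifted to zero and rounded to integer bins),
#' yielding the score-to-tail-probability table used for match p-values.
#' Discretization error on a word's total score is at most w/2 bins of
#' width `binSize`.
#'
#' @param pwm a [PWMotif-class]
#' @param bg a [ZeroOrderBackground-class]
#' @param pseudocount pseudocount (default 0.1)
#' @param bins number of discretization bins spanning the matrix's total
#'   score range (default 1000; must be >= 1000 for p-value accuracy
#'   guarantees)
#' @return a [MotifScoreMatrix-class]
#' @export
logOddsMatrix <- function(pwm, bg, pseudocount = 0.1, bins = 1000L) {
  stopifnot(is(pwm, "PWMotif"), is(bg, "ZeroOrderBackground"))
  if (any(bgFreq(bg) <= 0)) .stopf("background frequencies must be > 0")
  if (bins < 1) .stopf("bins must be positive")
  p <- probMatrix(pwm)
  f <- bgFreq(bg)
  S <- log2(sweep(sweep(p, 1, pseudocount * f, "+") / (1 + pseudocount),
                  1, f, "/"))
  w <- ncol(S)
  ## zero-probability entries (possible only with pseudocount 0) give
  ## -Inf; floor them just below the finite score range so such words can
  ## never outrank a finite-scoring word and tail p-values at attainable
  ## cutoffs stay exact
  if (any(!is.finite(S))) {
    finMin <- min(S[is.finite(S)])
    finRng <- max(S[is.finite(S)]) - finMin
    S[!is.finite(S)] <- finMin - w * (finRng + 1)
  }
  mins <- apply(S, 2, min)
  rng <- sum(apply(S, 2, max) - mins)
  binSize <- if (rng > 0) rng / bins else 1
  intS <- matrix(as.integer(round(sweep(S, 2, mins, "-") / binSize)), 4, w)
  rownames(intS) <- DNA_BASES
  ## exact DP over the discretized total-score distribution
  maxInt <- sum(apply(intS, 2, max))
  pmf <- numeric(maxInt + 1L)
  pmf[1] <- 1
  for (i in seq_len(w)) {
    newPmf <- numeric(maxInt + 1L)
    for (b in 1:4) {
      k <- intS[b, i]
      src <- pmf[seq_len(maxInt + 1L - k)]
      idx <- (k + 1L):(maxInt + 1L)
      newPmf[idx] <- newPmf[idx] + src * f[b]
    }
    pmf <- newPmf
  }
  tail <- rev(cumsum(rev(pmf)))
  tail <- pmin(tail, 1)
  new("MotifScoreMatrix", motif = pwm, background = bg, scores = S,
      intScores = intS, binSize = binSize, offset = sum(mins),
      tail = tail, pseudocount = pseudocount)
}

#' Exact match p-value for an integer score
#'
#' `P(total integer score >= k)` for a random background word, from the
#' dynamic-programming tail table.
#'
#' @param sm a [MotifScoreMatrix-class]
#' @param k integer score(s) (sum of discretized per-position scores)
#' @return numeric p-values in (0, 1]
#' @export
intScorePvalue <- function(sm, k) {
  maxInt <- length(sm@tail) - 1L
  k <- pmax(pmin(k, maxInt), 0L)
  sm@tail[k + 1L]
}

#' Integer and real score of a DNA word
#' @param sm a [MotifScoreMatrix-class]
#' @param word character word of the motif's width (A/C/G/T only)
#' @return list with `score` (real log2-odds), `intScore`, `pvalue`
#' @export
wordScore <- function(sm, word) {
  v <- encodeDNA(word)
  w <- ncol(sm@scores)
  if (length(v) != w || anyNA(v))
    .stopf("word must be %d unambiguous bases", w)
  idx <- cbind(v, seq_len(w))
  k <- sum(sm@intScores[idx])
  list(score = sum(sm@scores[idx]), intScore = k,
       pvalue = intScorePvalue(sm, k))
}

#' Integer score cutoff for a p-value threshold
#'
#' Smallest integer score whose tail probability does not exceed the
#' threshold; a word passes the scan iff its integer score reaches this
#' cutoff (equivalently, its p-value is <= the threshold).
#'
#' @param sm a [MotifScoreMatrix-class]
#' @param pThreshold p-value threshold in (0, 1)
#' @return list with `intCutoff` and `attained` (the actual tail
#'   probability at the cutoff, i.e. the per-word false-positive rate)
#' @export
scoreCutoff <- function(sm, pThreshold = 1e-4) {
  stopifnot(pThreshold > 0, pThreshold < 1)
  ok <- which(sm@tail <= pThreshold)
  if (length(ok) == 0L)
    return(list(intCutoff = length(sm@tail), attained = 0))
  k <- ok[1] - 1L
  list(intCutoff = k, attained = sm@tail[k + 1L])
}

#' Expected chance motif hits in a genome
#'
#' Expected number of background-generated windows passing the scan
#' threshold: the attained per-word false-positive rate times the number of
#' scanned windows on both strands.
#'
#' @param sm a [MotifScoreMatrix-class]
#' @param seqlen named chromosome lengths
#' @param pThreshold scan threshold
#' @return expected hit count (numeric)
#' @export
expectedChanceHits <- function(sm, seqlen, pThreshold = 1e-4) {
  w <- ncol(sm@scores)
  nPos <- sum(pmax(as.numeric(seqlen) - w + 1, 0))
  2 * nPos * scoreCutoff(sm, pThreshold)$attained
}

## integer scores of all windows of coded sequence v; NA where window has N
.windowIntScores <- function(intMat, v) {
  w <- ncol(intMat)
  n <- length(v) - w + 1L
  if (n < 1L) return(numeric(0))
  K <- numeric(n)
  for (i in seq_len(w)) K <- K + unname(intMat[, i][v[i:(i + n - 1L)]])
  K
}

## real scores at selected start positions
.realScoresAt <- function(S, v, at) {
  w <- ncol(S)
  sc <- numeric(length(at))
  for (i in seq_len(w)) sc <- sc + unname(S[, i][v[at + i - 1L]])
  sc
}

#' Scan a genome for motif matches
#'
#' Slides the scoring matrix over every position of every chromosome on
#' both strands (the reverse strand scores the reverse-complemented
#' window), emitting hits whose exact match p-value is at or below the
#' threshold. Windows containing ambiguous bases are skipped. With
#' `maxStrand`, when both strands pass at the same start only the
#' better-scoring strand is kept (ties keep +). Chromosomes shorter than
#' the motif are skipped with a notice.
#'
#' @param genome DNAStringSet
#' @param sm a [MotifScoreMatrix-class] (or list of them, scanned in turn)
#' @param pThreshold match p-value threshold (default 1e-4)
#' @param maxStrand collapse same-start double-strand hits (default TRUE)
#' @return GRanges of hits with columns `name` (motif id), `tf_name`,
#'   `score` (log2-odds) and `pvalue`, sorted by position
#' @export
scanGenome <- function(genome, sm, pThreshold = 1e-4, maxStrand = TRUE) {
  if (is.list(sm)) {
    res <- lapply(sm, scanGenome, genome = genome, pThreshold = pThreshold,
                  maxStrand = maxStrand)
    return(sort(do.call(c, unname(res)), ignore.strand = TRUE))
  }
  stopifnot(is(sm, "MotifScoreMatrix"))
  if (is.character(genome)) genome <- DNAStringSet(genome)
  w <- ncol(sm@scores)
  cut <- scoreCutoff(sm, pThreshold)$intCutoff
  seqlen <- genomeSeqlengths(genome)
  intF <- sm@intScores
  intR <- sm@intScores[4:1, w:1, drop = FALSE]  # reverse complement
  rownames(intR) <- DNA_BASES
  SF <- sm@scores
  SR <- sm@scores[4:1, w:1, drop = FALSE]
  rownames(SR) <- DNA_BASES

  hitList <- list()
  for (chrom in names(genome)) {
    if (seqlen[chrom] < w) {
      .msgf("chromosome %s shorter than motif width %d: skipped", chrom, w)
      next
    }
    v <- encodeDNA(as.character(genome[[chrom]]))
    kF <- .windowIntScores(intF, v)
    kR <- .windowIntScores(intR, v)
    passF <- !is.na(kF) & kF >= cut
    passR <- !is.na(kR) & kR >= cut
    at <- which(passF | passR)
    if (length(at) == 0L) next
    scF <- .realScoresAt(SF, v, at)
    scR <- .realScoresAt(SR, v, at)
    pF <- passF[at]; pR <- passR[at]
    if (maxStrand) {
      ## keep better-scoring strand; tie -> +
      usePlus <- pF & (!pR | scF >= scR)
      strand <- ifelse(usePlus, "+", "-")
      score <- ifelse(usePlus, scF, scR)
      k <- ifelse(usePlus, kF[at], kR[at])
      gr <- GRanges(chrom, IRanges(at, width = w), strand = strand,
                    seqlengths = seqlen)
      gr$score <- score
      gr$pvalue <- intScorePvalue(sm, k)
    } else {
      grF <- GRanges(chrom, IRanges(at[pF], width = w), strand = "+",
                     seqlengths = seqlen)
      grF$score <- scF[pF]; grF$pvalue <- intScorePvalue(sm, kF[at][pF])
      grR <- GRanges(chrom, IRanges(at[pR], width = w), strand = "-",
                     seqlengths = seqlen)
      grR$score <- scR[pR]; grR$pvalue <- intScorePvalue(sm, kR[at][pR])
      gr <- c(grF, grR)
    }
    hitList[[chrom]] <- gr
  }
  if (length(hitList) == 0L) {
    out <- GRanges(seqlengths = seqlen)
    out$name <- character(0); out$tf_name <- character(0)
    out$score <- numeric(0); out$pvalue <- numeric(0)
    return(out)
  }
  out <- do.call(c, unname(hitList))
  seqlevels(out) <- names(seqlen)
  seqlengths(out) <- seqlen
  mcols(out) <- DataFrame(name = rep(motifId(sm@motif), length(out)),
                          tf_name = rep(tfName(sm@motif), length(out)),
                          score = out$score, pvalue = out$pvalue)
  sort(out, ignore.strand = TRUE)
}

#' Write motif hits as BED6+2
#'
#' Columns: chrom, start, end, motif id, log2-odds score, strand, p-value,
#' TF name.
#' @param hits GRanges from [scanGenome()]
#' @param path output file
#' @return the path, invisibly
#' @export
writeHitsBed <- function(hits, path) {
  writeBed(hits, path, extraCols = c("pvalue", "tf_name"))
}

#' Read motif hits written by [writeHitsBed()]
#' @param path BED6+2 file
#' @param seqlen optional named chromosome lengths
#' @return GRanges with `name`, `score`, `pvalue`, `tf_name`
#' @export
readHitsBed <- function(path, seqlen = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    out <- GRanges(seqlengths = seqlen)
    out$name <- character(0); out$tf_name <- character(0)
    out$score <- numeric(0); out$pvalue <- numeric(0)
    return(out)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  start0 <- as.numeric(get(2)); end0 <- as.numeric(get(3))
  .checkBedCoords(start0, end0, path)
  gr <- GRanges(get(1), IRanges(start0 + 1, end0), strand = get(6))
  gr$name <- get(4)
  gr$tf_name <- get(8)
  gr$score <- as.numeric(get(5))
  gr$pvalue <- as.numeric(get(7))
  if (!is.null(seqlen)) {
    seqlevels(gr) <- union(names(seqlen), seqlevels(gr))
    seqlengths(gr)[names(seqlen)] <- seqlen
  }
  sort(gr, ignore.strand = TRUE)
}
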