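# Independent oracles: per-base bitmaps, exhaustive word enumeration and
# direct combinatorial summation. These never call the code paths they check.

# covered-base bitmap of a set of 1-based closed intervals on one chromosome
oracleBitmap <- function(starts, ends, len) {
  cov <- logical(len)
  for (i in seq_along(starts)) cov[starts[i]:ends[i]] <- TRUE
  cov
}

oracleCoveredBp <- function(gr, seqlen) {
  sum(vapply(names(seqlen), function(ch) {
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == ch]
    if (length(g) == 0L) return(0L)
    sum(oracleBitmap(GenomicRanges::start(g), GenomicRanges::end(g),
                     seqlen[[ch]]))
  }, integer(1)))
}

# exhaustive enumeration of all 4^w words: integer scores and probabilities
oracleWordDist <- function(intScores, bgFreq) {
  w <- ncol(intScores)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  ks <- rowSums(matrix(intScores[cbind(as.vector(grid),
                                       rep(seq_len(w), each = nrow(grid)))],
                       nrow(grid), w))
  wp <- apply(grid, 1, function(v) prod(bgFreq[v]))
  list(intScore = ks, prob = wp)
}

# one-sided binomial tail by direct pmf summation (log-space terms so
# large n does not overflow the binomial coefficient)
oracleBinomTail <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  sum(vapply(k:n, function(j)
    exp(lchoose(n, j) + j * log(p) + (n - j) * log1p(-p)), numeric(1)))
}

# hypergeometric upper tail by direct combinatorial summation
oracleHyperTail <- function(k, N, K, n) {
  if (k <= 0) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(j)
    choose(K, j) * choose(N - K, n - j), numeric(1))) / choose(N, n)
}

# two-sided Fisher p by enumerating the hypergeometric support at fixed
# margins; sums outcomes at most (1 + eps) times as probable as the
# observed table (the conventional two-sided definition)
oracleFisherTwoSided <- function(tab, eps = 1e-7) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
  pmf <- vapply(lo:hi, function(x)
    choose(c1, x) * choose(N - c1, r1 - x) / choose(N, r1), numeric(1))
  obs <- pmf[tab[1, 1] - lo + 1]
  sum(pmf[pmf <= obs * (1 + eps)])
}

# random PWM with controlled information content
randomPwm <- function(w, id = "Mr", concentration = 1) {
  m <- matrix(rgamma(4 * w, shape = concentration), 4, w)
  PWMotif(id, sweep(m, 2, colSums(m), "/"))
}

# random DNA string
randomSeq <- function(len, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs),
        collapse = "")
}
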