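#' Default TE library for the synthetic genome (species A)
#'
#' Type / family / repeat-class triples with copy numbers and mean lengths
#' sized so the default two-chromosome 750 kb genome carries roughly 9% TE
#' sequence, with two types (CELE1, Helitron2_CE) covering more than 20 kb so the
#' coverage gate of the enrichment filter cascade is exercisable.
#' @return data.frame with columns `type`, `family`, `repeat_class`,
#'   `mean_len`, `copies`
#' @export
defaultTeLibrary <- function() {
  data.frame(
    type = c("CELE1", "Tc1", "Helitron2_CE", "HelitronY2_CE", "CeRep55",
             "LINE2C", "CELE14B"),
    family = c("Tc1/mariner", "Tc1/mariner", "Helitron", "Helitron", "hAT",
               "CR1", "Tc1/mariner"),
    repeat_class = c("DNA", "DNA", "RC", "RC", "DNA", "LINE", "DNA"),
    mean_len = c(450, 300, 350, 300, 250, 400, 250),
    copies = c(52, 30, 65, 12, 12, 10, 8),
    stringsAsFactors = FALSE)
}

.defaultTeLibraryB <- function() {
  data.frame(
    type = c("DNA2-5_CB", "HelitronB_CB", "Tc1_CB"),
    family = c("Tc1/mariner", "Helitron", "Tc1/mariner"),
    repeat_class = c("DNA", "RC", "DNA"),
    mean_len = c(400, 350, 300),
    copies = c(30, 15, 15),
    stringsAsFactors = FALSE)
}

#' Synthetic-bundle configuration
#'
#' Assembles (and lightly validates) the plan for [generateBundle()]. The
#' defaults define a toy study: 2 x 375 kb chromosomes at C. elegans-like
#' base composition, ~9% TE content, 10 motifs of width 10, three motifs
#' planted at 22-fold in-TE enrichment (comfortably above the strict
#' >20-fold selection gate, as the study's selected motifs are), one motif reserved for the cross-species ortholog
#' plan, the rest placed uniformly; ATAC/ChIP summits covering planted
#' sites at fixed rates plus noise; and a second species sharing one-to-one
#' orthologs whose promoters carry similar-family TEs.
#'
#' @param seed master integer seed; every random draw flows from it through
#'   named substreams
#' @param chromLengths named integer chromosome lengths, species A
#' @param gc GC fraction of the background composition (default 0.36)
#' @param teLibrary TE library data.frame (see [defaultTeLibrary()])
#' @param nMotifs number of motifs
#' @param motifWidth motif width in bp
#' @param domProbRange range of the per-position dominant-base probability
#' @param plan data.frame with one row per motif: `te_type` (type the
#'   motif is enriched in, NA = uniform placement), `fold` (target realized
#'   fold enrichment), `n_planted` (planted site count), optional
#'   `outside_only`; NULL for the default plan
#' @param forceInTe minimum in-TE planted sites per motif (census
#'   property; ignored for null bundles)
#' @param nGenes,geneLenRange,operonFraction gene-model plan
#' @param atacCoverFrac fraction of planted sites covered by an ATAC summit
#' @param atacNoise,atacStages noise-summit count and stage count
#' @param chipCoverFrac,chipNoise per-TF ChIP coverage of that TF's planted
#'   sites and noise-summit count
#' @param speciesB generate the second species and ortholog map
#' @param chromLengthsB,teLibraryB,nGenesExtraB species-B plan
#' @param ortho list: `n` orthologs, `K`/`n_b`/`k` per-species and shared
#'   counts for the focal motif, `motif` (index of the focal motif),
#'   `similarFrac` fraction of shared pairs with same-family promoter TEs,
#'   `boundFrac` fraction of shared A-side hits covered by cognate ChIP
#' @param pThreshold scan p-value threshold assumed when planting
#'   high-scoring words and compensating for chance hits
#' @return a list of class `SynthConfig`
#' @export
synthConfig <- function(seed = 1,
                        chromLengths = c(chrI = 375000L, chrII = 375000L),
                        gc = 0.36,
                        teLibrary = defaultTeLibrary(),
                        nMotifs = 10, motifWidth = 10,
                        domProbRange = c(0.9, 0.97),
                        plan = NULL, forceInTe = 2,
                        nGenes = 400, geneLenRange = c(400, 900),
                        operonFraction = 0.15,
                        atacCoverFrac = 0.6, atacNoise = 300, atacStages = 3,
                        chipCoverFrac = 0.6, chipNoise = 150,
                        speciesB = TRUE,
                        chromLengthsB = c(cbI = 200000L, cbII = 200000L),
                        teLibraryB = .defaultTeLibraryB(),
                        nGenesExtraB = 30,
                        ortho = list(n = 150, K = 25, n_b = 20, k = 12,
                                     motif = 4, similarFrac = 0.3,
                                     boundFrac = 0.5),
                        pThreshold = 1e-4) {
  if (is.null(plan)) {
    plan <- data.frame(te_type = rep(NA_character_, nMotifs),
                       fold = rep(NA_real_, nMotifs),
                       n_planted = rep(60L, nMotifs))
    if (nMotifs >= 1) { plan$te_type[1] <- "CELE1"; plan$fold[1] <- 22 }
    if (nMotifs >= 2) { plan$te_type[2] <- "Helitron2_CE"; plan$fold[2] <- 22 }
    if (nMotifs >= 3) { plan$te_type[3] <- "Tc1"; plan$fold[3] <- 22 }
    plan$n_planted[!is.na(plan$te_type)] <- c(300L, 300L, 160L)[
      seq_len(sum(!is.na(plan$te_type)))]
    plan$outside_only <- FALSE
    if (speciesB && !is.null(ortho$motif) && nMotifs >= ortho$motif) {
      ## the ortholog focal motif is planted outside TEs (besides its
      ## promoter-TE sites) so promoter-TE sharing stays under plan control
      plan$n_planted[ortho$motif] <- 40L
      plan$outside_only[ortho$motif] <- TRUE
      plan$te_type[ortho$motif] <- NA_character_
      plan$fold[ortho$motif] <- NA_real_
    }
  }
  if (is.null(plan$outside_only)) plan$outside_only <- FALSE
  if (nrow(plan) != nMotifs) .stopf("plan must have one row per motif")
  bad <- !is.na(plan$te_type) & !(plan$te_type %in% teLibrary$type)
  if (any(bad)) .stopf("plan references unknown TE type %s",
                       plan$te_type[bad][1])
  if (speciesB && !is.null(ortho$motif) && ortho$motif > nMotifs)
    .stopf("ortho$motif exceeds nMotifs")
  if (speciesB && (ortho$k > min(ortho$K, ortho$n_b) ||
                   ortho$K > ortho$n || ortho$n_b > ortho$n))
    .stopf("infeasible ortholog plan (k <= min(K, n) <= N required)")
  structure(list(
    seed = seed, chromLengths = chromLengths, gc = gc,
    teLibrary = teLibrary, nMotifs = nMotifs, motifWidth = motifWidth,
    domProbRange = domProbRange, plan = plan, forceInTe = forceInTe,
    nGenes = nGenes, geneLenRange = geneLenRange,
    operonFraction = operonFraction, atacCoverFrac = atacCoverFrac,
    atacNoise = atacNoise, atacStages = atacStages,
    chipCoverFrac = chipCoverFrac, chipNoise = chipNoise,
    speciesB = speciesB, chromLengthsB = chromLengthsB,
    teLibraryB = teLibraryB, nGenesExtraB = nGenesExtraB, ortho = ortho,
    pThreshold = pThreshold), class = "SynthConfig")
}

## ---- internal helpers ------------------------------------------------
## The placement loops below deliberately work on plain per-chromosome
## occupancy masks instead of IRanges: they run hundreds of thousands of
## candidate checks.

## sample base codes (1..4) for one chromosome
.sampleCodes <- function(len, gc) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample.int(4L, len, replace = TRUE, prob = probs)
}

## species-state container: codes, TE table (data.frame), occupancy masks
.newSpeciesState <- function(seqlen) {
  st <- new.env(parent = emptyenv())
  st$seqlen <- seqlen
  st$teCov <- lapply(seqlen, function(L) logical(L))   # TE-covered bases
  st$plantCov <- lapply(seqlen, function(L) logical(L))
  st$te <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), te_type = character(0),
                      te_family = character(0), repeat_class = character(0),
                      stringsAsFactors = FALSE)
  st
}

.addTeRecord <- function(st, chrom, start, end, type, family, class) {
  st$te <- rbind(st$te, data.frame(chrom = chrom, start = start, end = end,
                                   te_type = type, te_family = family,
                                   repeat_class = class,
                                   stringsAsFactors = FALSE))
  st$teCov[[chrom]][start:end] <- TRUE
  invisible(st)
}

## place non-overlapping TE copies; margin keeps records non-abutting
.placeTeCopies <- function(st, lens, type, family, class, margin = 2L,
                           maxTry = 500L) {
  seqlen <- st$seqlen
  chroms <- names(seqlen)
  pChrom <- as.numeric(seqlen) / sum(as.numeric(seqlen))
  for (len in lens) {
    placed <- FALSE
    for (try in seq_len(maxTry)) {
      ci <- sample.int(length(chroms), 1, prob = pChrom)
      L <- seqlen[ci]
      if (L < len + 2L * margin) next
      stp <- sample.int(L - len - 2L * margin, 1) + margin
      span <- (stp - margin):(stp + len - 1L + margin)
      if (!any(st$teCov[[ci]][span])) {
        .addTeRecord(st, chroms[ci], stp, stp + len - 1L, type, family,
                     class)
        placed <- TRUE
        break
      }
    }
    if (!placed) .stopf("infeasible plan: could not place a %d bp TE", len)
  }
  invisible(st)
}

.teGRanges <- function(st) {
  te <- st$te
  gr <- GRanges(te$chrom, IRanges(te$start, te$end),
                seqlengths = st$seqlen)
  gr$te_type <- te$te_type
  gr$te_family <- te$te_family
  gr$repeat_class <- te$repeat_class
  sort(gr, ignore.strand = TRUE)
}

## collision against already-planted motif windows (base-occupancy mask)
.plantCollides <- function(st, chrom, stp, w) {
  any(st$plantCov[[chrom]][stp:(stp + w - 1L)])
}

.registerPlant <- function(st, chrom, stp, w) {
  st$plantCov[[chrom]][stp:(stp + w - 1L)] <- TRUE
}

## planting position strictly inside a TE record of the given type
.siteInTe <- function(st, type, w, maxTry = 500L) {
  te <- st$te[st$te$te_type == type & (st$te$end - st$te$start + 1L) >=
                w + 4L, ]
  if (nrow(te) == 0L) .stopf("no %s record wide enough to plant in", type)
  for (try in seq_len(maxTry)) {
    i <- sample.int(nrow(te), 1)
    stp <- te$start[i] + sample.int(te$end[i] - te$start[i] - w, 1)
    if (!.plantCollides(st, te$chrom[i], stp, w)) {
      .registerPlant(st, te$chrom[i], stp, w)
      return(list(chrom = te$chrom[i], start = stp))
    }
  }
  .stopf("infeasible plan: no room left inside %s", type)
}

## planting position with the window entirely outside all TEs
.siteOutsideTe <- function(st, w, maxTry = 500L) {
  seqlen <- st$seqlen
  pChrom <- as.numeric(seqlen) / sum(as.numeric(seqlen))
  for (try in seq_len(maxTry)) {
    ci <- sample.int(length(seqlen), 1, prob = pChrom)
    stp <- sample.int(seqlen[ci] - w, 1)
    chrom <- names(seqlen)[ci]
    if (!any(st$teCov[[chrom]][stp:(stp + w - 1L)]) &&
        !.plantCollides(st, chrom, stp, w)) {
      .registerPlant(st, chrom, stp, w)
      return(list(chrom = chrom, start = stp))
    }
  }
  .stopf("infeasible plan: no room outside TEs")
}

## uniform position regardless of TEs
.siteAnywhere <- function(st, w, maxTry = 500L) {
  seqlen <- st$seqlen
  pChrom <- as.numeric(seqlen) / sum(as.numeric(seqlen))
  for (try in seq_len(maxTry)) {
    ci <- sample.int(length(seqlen), 1, prob = pChrom)
    stp <- sample.int(seqlen[ci] - w, 1)
    chrom <- names(seqlen)[ci]
    if (!.plantCollides(st, chrom, stp, w)) {
      .registerPlant(st, chrom, stp, w)
      return(list(chrom = chrom, start = stp))
    }
  }
  .stopf("infeasible plan: genome too crowded")
}

## expected number of scan hits of the motif behind `sm` produced by a
## window overlapping one planted copy of `word` (any shift, either
## orientation) with random flanking bases; exact under the discretized
## score model. With `includeZero` the full-overlap window (shift 0) is
## counted too -- used for cross-motif contamination, where another
## motif's word can itself pass this motif's threshold.
.overlapHitRate <- function(sm, word, pThreshold, includeZero = FALSE) {
  S <- sm@intScores
  w <- ncol(S)
  f <- bgFreq(sm@background)
  cut <- scoreCutoff(sm, pThreshold)$intCutoff
  colMax <- apply(S, 2, max)
  colPmf <- lapply(seq_len(w), function(i) {
    pm <- numeric(colMax[i] + 1L)
    for (b in 1:4) pm[S[b, i] + 1L] <- pm[S[b, i] + 1L] + f[b]
    pm
  })
  sparseConv <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1L)
    for (i in which(b != 0)) {
      idx <- i:(i + length(a) - 1L)
      out[idx] <- out[idx] + b[i] * a
    }
    out
  }
  freeTail <- function(cols, need) {
    if (need <= 0) return(1)
    pm <- 1
    for (i in cols) pm <- sparseConv(pm, colPmf[[i]])
    if (need > length(pm) - 1L) return(0)
    sum(pm[(need + 1L):length(pm)])
  }
  total <- 0
  for (wd in list(word, rev(5L - word))) {
    if (includeZero &&
        sum(S[cbind(wd, seq_len(w))]) >= cut) total <- total + 1
    for (sh in seq_len(w - 1L)) {
      c1 <- sum(S[cbind(wd[(sh + 1L):w], seq_len(w - sh))])
      total <- total + freeTail((w - sh + 1L):w, cut - c1)
      c2 <- sum(S[cbind(wd[seq_len(w - sh)], (sh + 1L):w)])
      total <- total + freeTail(seq_len(sh), cut - c2)
    }
  }
  total
}

.motifConsensus <- function(sm) apply(probMatrix(sm@motif), 2, which.max)

## expected secondary hits of a motif around its own planted words
.expectedSecondaryRate <- function(sm, pThreshold) {
  .overlapHitRate(sm, .motifConsensus(sm), pThreshold, includeZero = FALSE)
}

## sample a word (integer codes) from the PWM's high-scoring tail
.sampleTopWord <- function(sm, maxP, maxTry = 300L) {
  p <- probMatrix(sm@motif)
  w <- ncol(p)
  cum <- apply(p, 2, cumsum)
  for (try in seq_len(maxTry)) {
    u <- runif(w)
    v <- colSums(cum < rep(u, each = 4L)) + 1L
    k <- sum(sm@intScores[cbind(v, seq_len(w))])
    if (intScorePvalue(sm, k) <= maxP) return(v)
  }
  v <- apply(p, 2, which.max)
  k <- sum(sm@intScores[cbind(v, seq_len(w))])
  if (intScorePvalue(sm, k) > maxP)
    .stopf("motif %s cannot reach p <= %g (too little information content)",
           motifId(sm@motif), maxP)
  v
}

## write word codes into the state's sequence
.plantWord <- function(st, chrom, start, v, strand) {
  if (is.null(st$codes)) return(invisible(NULL))
  if (strand == "-") v <- rev(5L - v)
  st$codes[[chrom]][start:(start + length(v) - 1L)] <- v
  invisible(NULL)
}

.codesToSeq <- function(codes) {
  DNAStringSet(vapply(codes, function(v)
    paste(DNA_BASES[v], collapse = ""), character(1)))
}

## generate gene models over the chromosomes, slot-based placement
.makeGenes <- function(seqlen, nGenes, lenRange, operonFraction, prefix) {
  chroms <- names(seqlen)
  total <- sum(as.numeric(seqlen))
  perChrom <- pmax(1L, round(nGenes * as.numeric(seqlen) / total))
  rows <- list()
  gi <- 0L
  for (ci in seq_along(chroms)) {
    n <- perChrom[ci]
    slot <- floor(seqlen[ci] / n)
    for (j in seq_len(n)) {
      gi <- gi + 1L
      hi <- max(lenRange[1], min(lenRange[2], slot - 60L))
      len <- sample(lenRange[1]:hi, 1)
      st <- (j - 1L) * slot + sample.int(max(slot - len - 40L, 1L), 1) + 20L
      rows[[gi]] <- data.frame(chrom = chroms[ci], start = st,
                               end = st + len - 1L,
                               strand = sample(c("+", "-"), 1),
                               gene_id = sprintf("%sg%04d", prefix, gi),
                               stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  ## operons: runs of 2-3 consecutive genes on one chromosome, same strand
  df$operon_id <- NA_character_
  oi <- 0L
  i <- 1L
  while (i <= nrow(df) - 2L) {
    if (runif(1) < operonFraction && df$chrom[i] == df$chrom[i + 1L]) {
      size <- sample(2:3, 1)
      idx <- i:min(i + size - 1L, nrow(df))
      idx <- idx[df$chrom[idx] == df$chrom[i]]
      if (length(idx) >= 2L) {
        oi <- oi + 1L
        df$operon_id[idx] <- sprintf("%sop%03d", prefix, oi)
        df$strand[idx] <- df$strand[i]
        i <- max(idx) + 1L
        next
      }
    }
    i <- i + 1L
  }
  genes <- GRanges(df$chrom, IRanges(df$start, df$end), strand = df$strand,
                   seqlengths = seqlen)
  genes$gene_id <- df$gene_id
  genes$operon_id <- df$operon_id

  ## sub-features: 5'UTR (60), 3'UTR (80), coding split in 2 exons + intron
  n <- nrow(df)
  plus <- df$strand == "+"
  u5 <- 60L; u3 <- 80L
  codLen <- (df$end - df$start + 1L) - u5 - u3
  intronLen <- pmax(40L, floor(codLen * 0.3))
  exonLen <- codLen - intronLen
  e1 <- floor(exonLen / 2); e2 <- exonLen - e1
  utr5s <- ifelse(plus, df$start, df$end - u5 + 1L)
  utr5e <- ifelse(plus, df$start + u5 - 1L, df$end)
  utr3s <- ifelse(plus, df$end - u3 + 1L, df$start)
  utr3e <- ifelse(plus, df$end, df$start + u3 - 1L)
  ex1s <- ifelse(plus, df$start + u5, df$end - u5 - e1 + 1L)
  ex1e <- ifelse(plus, df$start + u5 + e1 - 1L, df$end - u5)
  ex2s <- ifelse(plus, ex1e + intronLen + 1L, ex1s - intronLen - e2)
  ex2e <- ifelse(plus, ex1e + intronLen + e2, ex1s - intronLen - 1L)
  mk <- function(s, e) {
    g <- GRanges(rep(df$chrom, length(s) / n), IRanges(s, e),
                 strand = rep(df$strand, length(s) / n),
                 seqlengths = seqlen)
    g$gene_id <- rep(df$gene_id, length(s) / n)
    g
  }
  exons <- mk(c(ex1s, ex2s), c(ex1e, ex2e))
  intrs <- ifelse(plus, ex1e + 1L, ex2e + 1L)
  intre <- ifelse(plus, ex2s - 1L, ex1s - 1L)
  introns <- mk(intrs, intre)
  ops <- df[!is.na(df$operon_id), ]
  operons <- if (nrow(ops)) {
    sp <- split(ops, ops$operon_id)
    og <- do.call(c, unname(lapply(sp, function(x)
      GRanges(x$chrom[1], IRanges(min(x$start), max(x$end)),
              strand = x$strand[1], seqlengths = seqlen))))
    og$operon_id <- names(sp)
    og
  } else {
    og <- GRanges(seqlengths = seqlen); og$operon_id <- character(0); og
  }
  GeneModels(genes = genes, exons = exons, utr5 = mk(utr5s, utr5e),
             utr3 = mk(utr3s, utr3e), introns = introns, operons = operons)
}

## ---- generator -------------------------------------------------------

#' Generate a synthetic input bundle with ground truth
#'
#' Emits every input the pipeline consumes -- genome FASTA, TE annotation
#' table, gene/operon GFF-lite, motif file, per-stage ATAC summit BEDs,
#' per-TF ChIP summit BEDs, ortholog map and a second-species bundle --
#' together with ground-truth TSVs recording each planted motif site, its
#' TE membership and its accessibility/binding coverage. Identical seeds
#' give byte-identical output. Planted words are sampled from each PWM's
#' high-scoring tail so the scanner recovers them at the configured
#' p-value threshold, and planted in/out counts are set so the expected
#' realized fold enrichment (including chance hits) matches each motif's
#' target fold.
#'
#' @param config a [synthConfig()] plan
#' @param dir output directory (created if needed)
#' @param null plant every motif uniformly at random irrespective of TEs
#'   (calibration bundles); the enrichment plan and census forcing are
#'   ignored
#' @param writeFasta generate and write genome sequence (set FALSE for
#'   position-only calibration bundles, which need no sequence)
#' @return invisible list with `paths` (named file paths), `truth`
#'   (ground-truth tables and expectations), `config`, `pwms` and the
#'   composition `background`
#' @export
generateBundle <- function(config, dir, null = FALSE, writeFasta = TRUE) {
  stopifnot(inherits(config, "SynthConfig"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  seed <- config$seed
  w <- config$motifWidth

  ## -- motifs: drawn to be mutually dissimilar (low self- and
  ##    cross-overlap hit rates), as the scanning stage assumes
  ##    distinguishable motifs; the planting plan still compensates for
  ##    the residual overlap rates --
  bg <- ZeroOrderBackground(c(A = (1 - config$gc) / 2, C = config$gc / 2,
                              G = config$gc / 2, T = (1 - config$gc) / 2))
  motifDraws <- withSubSeed(seed, "motifs", {
    out <- list()
    outSm <- list()
    for (i in seq_len(config$nMotifs)) {
      accepted <- FALSE
      for (try in 1:300) {
        m <- sapply(seq_len(w), function(j) {
          d <- runif(1, config$domProbRange[1], config$domProbRange[2])
          v <- rep((1 - d) / 3, 4)
          v[sample.int(4L, 1)] <- d
          v
        })
        pw <- PWMotif(sprintf("M%03d_2.00", i), m,
                      tfName = sprintf("tf-%02d", i))
        smI <- logOddsMatrix(pw, bg)
        if (.expectedSecondaryRate(smI, config$pThreshold) > 0.05) next
        consI <- .motifConsensus(smI)
        clash <- FALSE
        for (smP in outSm) {
          if (.overlapHitRate(smI, .motifConsensus(smP), config$pThreshold,
                              includeZero = TRUE) > 0.02 ||
              .overlapHitRate(smP, consI, config$pThreshold,
                              includeZero = TRUE) > 0.02) {
            clash <- TRUE
            break
          }
        }
        if (clash) next
        out[[i]] <- pw
        outSm[[i]] <- smI
        accepted <- TRUE
        break
      }
      if (!accepted)
        .stopf("could not sample %d mutually dissimilar motifs",
               config$nMotifs)
    }
    list(pwms = out, sms = outSm)
  })
  pwms <- motifDraws$pwms
  sms <- motifDraws$sms
  names(pwms) <- vapply(pwms, motifId, character(1))
  names(sms) <- names(pwms)

  ## -- species skeletons (genome, TEs, genes) --
  stA <- .makeSpeciesBase(config, seed, "A", config$chromLengths,
                          config$teLibrary, config$nGenes, writeFasta)
  stB <- NULL
  if (config$speciesB)
    stB <- .makeSpeciesBase(config, seed, "B", config$chromLengthsB,
                            config$teLibraryB,
                            config$ortho$n + config$nGenesExtraB, writeFasta)

  ## -- ortholog promoter-TE planting (before the main plan, so planted
  ##    "outside" sites can never end up inside later-added TEs) --
  orthoTruth <- NULL
  sitesA <- NULL; sitesB <- NULL
  if (config$speciesB) {
    or <- .plantOrthologs(config, seed, stA, stB,
                          sms[[config$ortho$motif]], null)
    orthoTruth <- or$truth
    sitesA <- or$sitesA
    sitesB <- or$sitesB
  }

  ## -- main planting plan (species A) --
  pm <- withSubSeed(seed, "plantA",
                    .plantMainPlan(config, stA, pwms, sms, null))
  sitesA <- rbind(sitesA, pm$sites)
  expected <- pm$expected

  ## -- summits (species A) --
  su <- withSubSeed(seed, "summitsA", .makeSummits(config, stA, sitesA))
  sitesA <- su$sites
  if (!is.null(orthoTruth))
    orthoTruth$pairs$bound_a <- orthoTruth$pairs$idA %in%
      sitesA$gene_id[sitesA$bound & !is.na(sitesA$gene_id)]

  truth <- list(sitesA = sitesA, sitesB = sitesB, expectedA = expected,
                ortho = orthoTruth)

  ## -- write files --
  fp <- function(x) file.path(dir, x)
  paths <- list()
  if (writeFasta) {
    seqsA <- .codesToSeq(stA$codes)
    names(seqsA) <- names(config$chromLengths)
    writeXStringSet(seqsA, fp("genome_a.fa"), width = 70L)
    paths$genomeA <- fp("genome_a.fa")
    if (!is.null(stB)) {
      seqsB <- .codesToSeq(stB$codes)
      names(seqsB) <- names(config$chromLengthsB)
      writeXStringSet(seqsB, fp("genome_b.fa"), width = 70L)
      paths$genomeB <- fp("genome_b.fa")
    }
  }
  paths$teA <- writeTeTable(.teGRanges(stA), fp("te_a.tsv"))
  paths$genesA <- writeGffLite(stA$genes, fp("genes_a.gff"))
  paths$motifs <- writeCisbpChen(pwms, fp("motifs.chen"))
  if (!is.null(stB)) {
    paths$teB <- writeTeTable(.teGRanges(stB), fp("te_b.tsv"))
    paths$genesB <- writeGffLite(stB$genes, fp("genes_b.gff"))
    con <- file(fp("orthologs.tsv"), "wt")
    write.table(orthoTruth$map, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    close(con)
    paths$orthologs <- fp("orthologs.tsv")
  }
  paths$atac <- character(0)
  for (s in seq_len(config$atacStages)) {
    f <- fp(sprintf("atac_stage%d.bed", s))
    .writeSummitBed(su$atac[[s]], f)
    paths$atac <- c(paths$atac, f)
  }
  paths$chip <- character(0)
  for (m in names(su$chip)) {
    f <- fp(sprintf("chip_%s.bed", m))
    .writeSummitBed(su$chip[[m]], f)
    paths$chip <- c(paths$chip, setNames(f, m))
  }
  paths$truthSitesA <- .writeTsv(truth$sitesA, fp("truth_sites_a.tsv"),
                                 comment = "1-based starts")
  paths$truthExpected <- .writeTsv(expected, fp("truth_expected.tsv"))
  if (!is.null(stB)) {
    paths$truthSitesB <- .writeTsv(truth$sitesB, fp("truth_sites_b.tsv"),
                                   comment = "1-based starts")
    paths$truthOrtho <- .writeTsv(orthoTruth$pairs,
                                  fp("truth_orthologs.tsv"))
  }
  invisible(list(paths = paths, truth = truth, config = config,
                 pwms = pwms, background = bg))
}

#' Generate a null calibration bundle
#'
#' As [generateBundle()] but with the planting plan disabled: every motif
#' is placed uniformly at random irrespective of TEs, so downstream
#' binomial / hypergeometric / Fisher statistics see data generated under
#' their null.
#'
#' @param config a [synthConfig()] plan
#' @param dir output directory
#' @param writeFasta generate genome sequence (FALSE for position-only
#'   calibration)
#' @return as [generateBundle()]
#' @export
nullBundle <- function(config, dir, writeFasta = TRUE) {
  generateBundle(config, dir, null = TRUE, writeFasta = writeFasta)
}

## genome sequence + TE track + gene models for one species
.makeSpeciesBase <- function(config, seed, tag, seqlen, teLib, nGenes,
                             writeFasta) {
  st <- .newSpeciesState(seqlen)
  if (writeFasta) {
    st$codes <- withSubSeed(seed, paste0("genome", tag),
                            lapply(as.integer(seqlen), .sampleCodes,
                                   gc = config$gc))
    names(st$codes) <- names(seqlen)
  }
  withSubSeed(seed, paste0("te", tag), {
    for (i in seq_len(nrow(teLib))) {
      lens <- pmax(config$motifWidth + 6L,
                   round(runif(teLib$copies[i], 0.6, 1.4) *
                           teLib$mean_len[i]))
      .placeTeCopies(st, lens, teLib$type[i], teLib$family[i],
                     teLib$repeat_class[i])
    }
  })
  st$genes <- withSubSeed(seed, paste0("genes", tag),
                          .makeGenes(seqlen, nGenes, config$geneLenRange,
                                     config$operonFraction,
                                     prefix = if (tag == "B") "b" else "a"))
  st
}

## the per-motif enrichment/uniform planting plan, species A. Planted
## in/out counts are solved so the expected realized fold -- including
## chance hits, self-overlap secondary hits and cross-motif contamination
## from other motifs' planted words -- matches each motif's target.
.plantMainPlan <- function(config, st, pwms, sms, null) {
  w <- config$motifWidth
  n <- config$nMotifs
  genomeBp <- sum(as.numeric(st$seqlen))
  typeBp <- tapply(st$te$end - st$te$start + 1, st$te$te_type, sum)
  teBpTotal <- sum(typeBp)

  plan <- config$plan
  enriched <- !null & !is.na(plan$te_type)
  p0 <- ifelse(enriched, unname(typeBp[plan$te_type]) / genomeBp, NA)
  efp <- vapply(sms, expectedChanceHits, numeric(1), seqlen = st$seqlen,
                pThreshold = config$pThreshold)
  selfR <- if (any(enriched))
    vapply(sms, .expectedSecondaryRate, numeric(1),
           pThreshold = config$pThreshold) else numeric(n)
  ## cross-motif contamination rates: C[m, g] = expected hits of motif m
  ## per planted site of motif g
  C <- matrix(0, n, n)
  if (any(enriched) && n > 1) {
    cons <- lapply(sms, .motifConsensus)
    for (m in which(enriched)) for (g in seq_len(n)) if (g != m)
      C[m, g] <- .overlapHitRate(sms[[m]], cons[[g]], config$pThreshold,
                                 includeZero = TRUE)
  }

  ## two passes: cross terms need the other motifs' in/out splits
  nIn <- integer(n)
  for (pass in 1:2) {
    for (m in which(enriched)) {
      grow <- 1 + selfR[m]
      nPl <- plan$n_planted[m]
      others <- setdiff(seq_len(n), m)
      crossTotal <- sum(plan$n_planted[others] * C[m, others])
      ## expected planted-site count of other motifs inside m's type
      inType <- vapply(others, function(g) {
        if (!null && isTRUE(plan$te_type[g] == plan$te_type[m]))
          return(as.numeric(nIn[g]))
        if (!null && !is.na(plan$te_type[g])) return(0)
        if (isTRUE(plan$outside_only[g]) && !null) return(0)
        nForce <- if (null) 0 else min(config$forceInTe, plan$n_planted[g])
        nForce * unname(typeBp[plan$te_type[m]]) / teBpTotal +
          (plan$n_planted[g] - nForce) * p0[m]
      }, numeric(1))
      crossIn <- sum(inType * C[m, others])
      val <- (plan$fold[m] * p0[m] *
                (nPl * grow + efp[m] + crossTotal) -
                p0[m] * efp[m] - crossIn) / grow
      nIn[m] <- max(0L, min(nPl, round(val)))
    }
  }

  rows <- list()
  planRows <- list()
  for (mi in seq_len(n)) {
    pw <- pwms[[mi]]; sm <- sms[[mi]]
    nPl <- plan$n_planted[mi]
    if (enriched[mi]) {
      planRows[[length(planRows) + 1L]] <- data.frame(
        name = motifId(pw), te_type = plan$te_type[mi],
        target_fold = plan$fold[mi], n_planted = nPl, n_in = nIn[mi],
        p0 = p0[mi], expected_chance_hits = efp[mi],
        secondary_rate = selfR[mi], stringsAsFactors = FALSE)
      groups <- list(list(kind = "in_te", n = nIn[mi],
                          type = plan$te_type[mi]),
                     list(kind = "outside", n = nPl - nIn[mi], type = NA))
    } else {
      outsideOnly <- isTRUE(plan$outside_only[mi]) && !null
      nForce <- if (null || outsideOnly) 0L else min(config$forceInTe, nPl)
      groups <- list(list(kind = "force_te", n = nForce, type = NA),
                     list(kind = if (outsideOnly) "outside" else "uniform",
                          n = nPl - nForce, type = NA))
    }
    for (g in groups) {
      if (g$n == 0L) next
      pos <- .placeSiteGroup(st, g$kind, g$type, g$n, w)
      std <- sample(c("+", "-"), g$n, replace = TRUE)
      if (!is.null(st$codes)) {
        for (i in seq_len(g$n)) {
          word <- .sampleTopWord(sm, config$pThreshold * 0.1)
          .plantWord(st, pos$chrom[i], pos$start[i], word, std[i])
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        name = motifId(pw), chrom = pos$chrom, start = pos$start,
        strand = std, planted_in = g$kind, gene_id = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  list(sites = do.call(rbind, rows),
       expected = if (length(planRows)) do.call(rbind, planRows) else
         data.frame(name = character(0), te_type = character(0),
                    target_fold = numeric(0), n_planted = integer(0),
                    n_in = integer(0), p0 = numeric(0),
                    expected_chance_hits = numeric(0),
                    secondary_rate = numeric(0)))
}

## place n non-colliding motif windows of one kind; the per-chromosome
## planted mask is hoisted into a local vector so the per-site writes are
## in place rather than copying the whole mask. In position-only bundles
## (no sequence) sites may overlap: no words compete for bases, and
## independent placement is exactly what the calibration null assumes.
.placeSiteGroup <- function(st, kind, type, n, w, maxTry = 1000L) {
  seqlen <- st$seqlen
  chroms <- names(seqlen)
  useMask <- !is.null(st$codes)
  nPer <- tabulate(sample.int(length(chroms), n, replace = TRUE,
                              prob = as.numeric(seqlen)), length(chroms))
  out <- vector("list", length(chroms))
  for (j in seq_along(chroms)) {
    m <- nPer[j]
    if (m == 0L) next
    ch <- chroms[j]
    L <- seqlen[[j]]
    mask <- if (useMask) st$plantCov[[ch]] else FALSE
    teM <- st$teCov[[ch]]
    typeM <- NULL
    if (kind == "in_te") {
      typeM <- logical(L)
      te <- st$te[st$te$te_type == type & st$te$chrom == ch, ]
      for (i in seq_len(nrow(te))) typeM[te$start[i]:te$end[i]] <- TRUE
    }
    starts <- integer(m)
    for (i in seq_len(m)) {
      placed <- FALSE
      for (try in seq_len(maxTry)) {
        stp <- sample.int(L - w, 1)
        win <- stp:(stp + w - 1L)
        ok <- (!useMask || !any(mask[win])) && switch(kind,
          in_te = stp > 1L && all(typeM[(stp - 1L):(stp + w)]),
          force_te = stp > 1L && all(teM[(stp - 1L):(stp + w)]),
          outside = !any(teM[win]),
          uniform = TRUE)
        if (ok) {
          ## stamp a w-1 guard band so no window spans two planted words
          if (useMask)
            mask[max(1L, stp - w + 1L):min(L, stp + 2L * w - 2L)] <- TRUE
          starts[i] <- stp
          placed <- TRUE
          break
        }
      }
      if (!placed)
        .stopf("infeasible plan: no room for a '%s' site on %s", kind, ch)
    }
    if (useMask) st$plantCov[[ch]] <- mask
    out[[j]] <- data.frame(chrom = ch, start = starts,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## plant the focal motif in promoter TEs of selected ortholog genes in
## both species, with controlled sharing and family similarity
.plantOrthologs <- function(config, seed, stA, stB, sm, null) {
  o <- config$ortho
  w <- config$motifWidth

  ## ortholog genes whose (inclusive, 2500 bp) promoter window fully
  ## contains one of the planted hits -- the realized feature sets
  memberGenes <- function(st, sitesDf, orthIds) {
    if (is.null(sitesDf) || nrow(sitesDf) == 0L) return(character(0))
    genes <- geneSpans(st$genes)
    genes <- genes[genes$gene_id %in% orthIds]
    plus <- as.logical(strand(genes) == "+")
    sl <- st$seqlen[as.character(seqnames(genes))]
    pst <- ifelse(plus, pmax(start(genes) - 2500L, 1L), end(genes) + 1L)
    pen <- ifelse(plus, start(genes) - 1L, pmin(end(genes) + 2500L, sl))
    keep <- pst <= pen
    pw_ <- GRanges(seqnames(genes)[keep], IRanges(pst[keep], pen[keep]))
    hg <- GRanges(sitesDf$chrom, IRanges(sitesDf$start,
                                         sitesDf$start + w - 1L))
    ov <- findOverlaps(hg, pw_, type = "within", ignore.strand = TRUE)
    sort(unique(genes$gene_id[keep][subjectHits(ov)]))
  }

  withSubSeed(seed, "ortho", {
    idsA <- geneSpans(stA$genes)$gene_id
    idsB <- geneSpans(stB$genes)$gene_id
    orthA <- sort(sample(idsA, o$n))
    orthB <- sort(sample(idsB, o$n))
    map <- data.frame(idA = orthA, idB = orthB, stringsAsFactors = FALSE)

    if (null) {
      setA <- sample(orthA, o$K)
      setB <- sample(orthB, o$n_b)
    } else {
      setA <- sample(orthA, o$K)
      shared <- sample(setA, o$k)
      restB <- map$idB[match(sample(setdiff(orthA, setA), o$n_b - o$k),
                             map$idA)]
      setB <- c(map$idB[match(shared, map$idA)], restB)
    }
    sharedA <- map$idA[map$idA %in% setA & map$idB %in% setB]
    nSim <- round(o$similarFrac * length(sharedA))
    famPlan <- setNames(rep("different", length(sharedA)), sharedA)
    if (nSim > 0) famPlan[seq_len(nSim)] <- "similar"

    ## last library type of the family, so promoter TEs never inflate
    ## the genome share of an enrichment-plan focal type (listed first)
    typeForFam <- function(lib, fam) {
      cand <- lib$type[lib$family == fam]
      if (length(cand) == 0L) lib$type[nrow(lib)] else cand[length(cand)]
    }
    plantSide <- function(st, set, side) {
      genes <- geneSpans(st$genes)
      lib <- if (side == "A") config$teLibrary else config$teLibraryB
      rows <- list()
      for (g in set) {
        gi <- which(genes$gene_id == g)
        plus <- as.logical(strand(genes)[gi] == "+")
        chrom <- as.character(seqnames(genes))[gi]
        L <- st$seqlen[chrom]
        teLen <- 220L
        ## A-side promoter TEs are Tc1/mariner; B-side pairs planned as
        ## family-different get a Helitron instead
        fam <- if (side == "A") "Tc1/mariner" else {
          gA <- map$idA[match(g, map$idB)]
          if (!is.na(gA) && gA %in% names(famPlan) &&
              famPlan[gA] == "different") "Helitron" else "Tc1/mariner"
        }
        placed <- FALSE
        for (offset in c(700L, 950L, 1400L, 1900L, 450L, 550L, 800L,
                         1100L, 1250L, 1550L, 1700L, 2050L, 2200L, 350L,
                         600L, 1000L, 1800L, 2350L)) {
          s0 <- if (plus) start(genes)[gi] - offset
                else end(genes)[gi] + offset - teLen + 1L
          e0 <- s0 + teLen - 1L
          if (s0 < 2L || e0 > L - 1L) next
          if (any(st$teCov[[chrom]][(s0 - 1L):(e0 + 1L)])) next
          tt <- typeForFam(lib, fam)
          .addTeRecord(st, chrom, s0, e0, tt, fam,
                       lib$repeat_class[match(tt, lib$type)])
          hitSt <- s0 + 5L + sample.int(teLen - w - 10L, 1)
          .registerPlant(st, chrom, hitSt, w)
          std <- sample(c("+", "-"), 1)
          if (!is.null(st$codes)) {
            word <- .sampleTopWord(sm, config$pThreshold * 0.1)
            .plantWord(st, chrom, hitSt, word, std)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            name = motifId(sm@motif), chrom = chrom, start = hitSt,
            strand = std, planted_in = "promoter_te", gene_id = g,
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed) .stopf("no room for a promoter TE upstream of %s", g)
      }
      do.call(rbind, rows)
    }

    sitesA <- plantSide(stA, setA, "A")
    sitesB <- plantSide(stB, setB, "B")

    ## realized sets: a planted hit can also fall in a neighbouring
    ## ortholog gene's promoter window, so membership is recomputed
    realA <- memberGenes(stA, sitesA, orthA)
    realB <- memberGenes(stB, sitesB, orthB)
    pairs <- data.frame(idA = map$idA, idB = map$idB,
                        in_a = map$idA %in% realA,
                        in_b = map$idB %in% realB,
                        stringsAsFactors = FALSE)
    pairs$shared <- pairs$in_a & pairs$in_b
    pairs$family_similar <- ifelse(
      pairs$shared & pairs$idA %in% names(famPlan),
      unname(famPlan[pairs$idA]) == "similar", NA)
    list(truth = list(map = map, pairs = pairs,
                      motif = motifId(sm@motif),
                      plannedA = sort(setA), plannedB = sort(setB),
                      setA = realA, setB = realB),
         sitesA = sitesA, sitesB = sitesB)
  })
}

## ATAC and ChIP summit construction with coverage bookkeeping
.makeSummits <- function(config, st, sites) {
  seqlen <- st$seqlen
  w <- config$motifWidth
  n <- nrow(sites)
  sites$accessible <- logical(n)
  sites$bound <- logical(n)
  teOv <- vapply(seq_len(n), function(i)
    all(st$teCov[[sites$chrom[i]]][sites$start[i]:(sites$start[i] + w - 1L)]),
    logical(1))
  ## accessible: per motif force one in-TE site, then random coverage
  for (m in unique(sites$name)) {
    idx <- which(sites$name == m)
    cover <- idx[runif(length(idx)) < config$atacCoverFrac]
    inTe <- idx[teOv[idx]]
    if (length(inTe) > 0 && !any(teOv[cover]))
      cover <- c(cover, inTe[1])
    sites$accessible[cover] <- TRUE
  }
  ## bound: per motif coverage; promoter_te sites of the focal motif get
  ## boundFrac coverage so the cross-species bound-shared count is planted
  for (m in unique(sites$name)) {
    idx <- which(sites$name == m)
    prom <- idx[sites$planted_in[idx] == "promoter_te"]
    rest <- setdiff(idx, prom)
    cover <- rest[runif(length(rest)) < config$chipCoverFrac]
    if (length(prom) > 0) {
      nb <- round(config$ortho$boundFrac * length(prom))
      cover <- c(cover, prom[seq_len(nb)])
    }
    sites$bound[cover] <- TRUE
  }
  mkSummit <- function(chrom, pos) {
    pos <- pmax(1L, pmin(pos, seqlen[chrom]))
    GRanges(chrom, IRanges(pos, pos), seqlengths = seqlen)
  }
  center <- sites$start + floor(w / 2)
  acc <- which(sites$accessible)
  stage <- sample.int(config$atacStages, length(acc), replace = TRUE)
  noise <- function(count) {
    ch <- sample(names(seqlen), count, replace = TRUE,
                 prob = as.numeric(seqlen))
    pos <- vapply(ch, function(x) sample.int(seqlen[x] - 100L, 1) + 50L,
                  integer(1))
    mkSummit(ch, pos)
  }
  atac <- lapply(seq_len(config$atacStages), function(s) {
    sel <- acc[stage == s]
    sort(c(mkSummit(sites$chrom[sel], center[sel]),
           noise(ceiling(config$atacNoise / config$atacStages))))
  })
  chip <- lapply(setNames(nm = sort(unique(sites$name))), function(m) {
    sel <- which(sites$name == m & sites$bound)
    sort(c(mkSummit(sites$chrom[sel], center[sel]),
           noise(config$chipNoise)))
  })
  list(sites = sites, atac = atac, chip = chip)
}

.writeSummitBed <- function(gr, path) {
  gr <- sort(gr, ignore.strand = TRUE)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = start(gr),
                   name = sprintf("summit_%05d", seq_along(gr)),
                   score = 0L, strand = ".")
  con <- file(path, "wt")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
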