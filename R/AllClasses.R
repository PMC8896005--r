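#' @import methods
#' @importClassesFrom GenomicRanges GRanges
NULL

#' PWMotif: a position weight matrix with identifiers
#'
#' Per-position base-probability model of a transcription factor's binding
#' preference. The matrix is stored base-by-position (4 rows A, C, G, T).
#'
#' @slot id motif identifier (Cis-BP style, e.g. "M0047_2.00")
#' @slot tfName name of the transcription factor the motif belongs to
#' @slot matrix numeric 4 x w probability matrix, rows named A, C, G, T;
#'   every column sums to 1
#' @export
setClass("PWMotif", representation(
  id = "character", tfName = "character", matrix = "matrix"
))

setValidity("PWMotif", function(object) {
  m <- object@matrix
  if (!is.numeric(m) || nrow(m) != 4L)
    return("matrix must be numeric with 4 rows (A, C, G, T)")
  if (ncol(m) < 1L) return("motif width must be >= 1")
  if (any(m < 0)) return("probabilities must be non-negative")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-6))
    return(sprintf("column %d does not sum to 1 (sum = %.8f)",
                   which(abs(cs - 1) > 1e-6)[1], cs[which(abs(cs - 1) > 1e-6)[1]]))
  if (length(object@id) != 1L) return("id must be a single string")
  TRUE
})

#' Construct a PWMotif
#'
#' @param id motif identifier
#' @param matrix 4 x w (rows A,C,G,T) or w x 4 (columns A,C,G,T) probability
#'   matrix; a w x 4 matrix is transposed on ingest
#' @param tfName transcription factor name (defaults to the id)
#' @return a [PWMotif-class] object
#' @examples
#' pwm <- PWMotif("M1", matrix(0.25, 4, 6, dimnames = list(c("A","C","G","T"), NULL)))
#' motifWidth(pwm)
#' @export
PWMotif <- function(id, matrix, tfName = id) {
  if (ncol(matrix) == 4L && nrow(matrix) != 4L) matrix <- t(matrix)
  rownames(matrix) <- DNA_BASES
  ## renormalize tiny floating drift
  cs <- colSums(matrix)
  if (any(abs(cs - 1) > 1e-6) && all(abs(cs - 1) < 1e-3))
    matrix <- sweep(matrix, 2, cs, "/")
  new("PWMotif", id = as.character(id), tfName = as.character(tfName),
      matrix = matrix)
}

#' @describeIn PWMotif-class motif identifier
#' @param x a PWMotif
#' @export
motifId <- function(x) x@id

#' @describeIn PWMotif-class transcription factor name
#' @export
tfName <- function(x) x@tfName

#' @describeIn PWMotif-class motif width (number of positions)
#' @export
motifWidth <- function(x) ncol(x@matrix)

#' @describeIn PWMotif-class 4 x w probability matrix (rows A, C, G, T)
#' @export
probMatrix <- function(x) x@matrix

#' @describeIn PWMotif-class consensus sequence (highest-probability base per
#'   position, ties broken alphabetically)
#' @export
consensusWord <- function(x) {
  paste(DNA_BASES[apply(x@matrix, 2, which.max)], collapse = "")
}

setMethod("show", "PWMotif", function(object) {
  cat(sprintf("PWMotif %s (TF %s), width %d, consensus %s\n",
              object@id, object@tfName, motifWidth(object),
              consensusWord(object)))
})

#' ZeroOrderBackground: mononucleotide background model
#'
#' Zero-order Markov model of genomic base composition, the null model for
#' motif scoring. Frequencies are pooled over both strands by default, so
#' freq(A) = freq(T) and freq(C) = freq(G).
#'
#' @slot freq named numeric of length 4 (A, C, G, T); strictly positive,
#'   summing to 1
#' @export
setClass("ZeroOrderBackground", representation(freq = "numeric"))

setValidity("ZeroOrderBackground", function(object) {
  f <- object@freq
  if (length(f) != 4L || !identical(names(f), DNA_BASES))
    return("freq must be a length-4 vector named A, C, G, T")
  if (any(f <= 0)) return("all background frequencies must be > 0")
  if (abs(sum(f) - 1) > 1e-8) return("frequencies must sum to 1")
  TRUE
})

#' Construct a zero-order background model
#' @param freq numeric of length 4, frequencies of A, C, G, T (normalized
#'   on ingest)
#' @return a [ZeroOrderBackground-class] object
#' @export
ZeroOrderBackground <- function(freq = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  freq <- as.numeric(freq)
  names(freq) <- DNA_BASES
  new("ZeroOrderBackground", freq = freq / sum(freq))
}

#' @describeIn ZeroOrderBackground-class base frequencies
#' @param x a ZeroOrderBackground
#' @export
bgFreq <- function(x) x@freq

setMethod("show", "ZeroOrderBackground", function(object) {
  cat("ZeroOrderBackground:",
      paste(sprintf("%s=%.4f", DNA_BASES, object@freq), collapse = " "), "\n")
})

#' MotifScoreMatrix: log-odds scores with an exact p-value table
#'
#' The scoring object derived from a [PWMotif-class] and a
#' [ZeroOrderBackground-class]: real-valued log2-odds scores, a discretized
#' integer copy, and the exact tail distribution of the total integer score
#' under the background (computed by dynamic programming), which maps any
#' score to its match p-value.
#'
#' @slot motif the source PWMotif
#' @slot background the ZeroOrderBackground used
#' @slot scores numeric 4 x w log2-odds score matrix
#' @slot intScores integer 4 x w discretized score matrix (per-position
#'   minimum shifted to 0)
#' @slot binSize numeric width of one discretization bin in score units
#' @slot offset numeric sum of per-position minimum scores (integer score 0
#'   corresponds to real score `offset`)
#' @slot tail numeric vector; `tail[k + 1]` = P(total integer score >= k)
#'   under the background
#' @slot pseudocount pseudocount used in the log-odds transform
#' @export
setClass("MotifScoreMatrix", representation(
  motif = "PWMotif", background = "ZeroOrderBackground",
  scores = "matrix", intScores = "matrix", binSize = "numeric",
  offset = "numeric", tail = "numeric", pseudocount = "numeric"
))

setValidity("MotifScoreMatrix", function(object) {
  if (any(diff(object@tail) > 1e-12))
    return("p-value table must be monotone non-increasing in score")
  if (abs(object@tail[1] - 1) > 1e-9)
    return("tail at minimal score must be 1")
  TRUE
})

setMethod("show", "MotifScoreMatrix", function(object) {
  w <- ncol(object@scores)
  cat(sprintf(
    "MotifScoreMatrix for %s: width %d, best score %.3f bits, p(best) = %.3g\n",
    object@motif@id, w, maxScore(object),
    object@tail[sum(apply(object@intScores, 2, max)) + 1L]))
})

#' @describeIn MotifScoreMatrix-class best attainable log2-odds score
#' @param x a MotifScoreMatrix
#' @export
maxScore <- function(x) sum(apply(x@scores, 2, max))

#' @describeIn MotifScoreMatrix-class the source motif
#' @export
scoreMotif <- function(x) x@motif

#' GeneModels: protein-coding gene structures
#'
#' Gene spans with strand plus sub-feature tracks (coding exons, 5'/3' UTRs,
#' introns) and optional operon spans. All ranges are 1-based closed
#' (GRanges convention); file readers and writers convert from/to BED-style
#' half-open coordinates at the boundary.
#'
#' @slot genes GRanges of gene spans; mcols `gene_id`, `operon_id`
#'   (NA when the gene is not in an operon)
#' @slot exons,utr5,utr3,introns GRanges of sub-features; mcols `gene_id`
#' @slot operons GRanges of operon spans; mcols `operon_id`
#' @export
setClass("GeneModels", representation(
  genes = "GRanges", exons = "GRanges", utr5 = "GRanges",
  utr3 = "GRanges", introns = "GRanges", operons = "GRanges"
))

setValidity("GeneModels", function(object) {
  g <- object@genes
  if (is.null(g$gene_id)) return("genes must carry a gene_id column")
  if (anyDuplicated(g$gene_id)) return("gene ids must be unique")
  if (any(GenomicRanges::strand(g) == "*"))
    return("all genes must be stranded (+ or -)")
  for (nm in c("exons", "utr5", "utr3", "introns")) {
    sub <- slot(object, nm)
    if (length(sub) == 0L) next
    if (is.null(sub$gene_id)) return(sprintf("%s must carry gene_id", nm))
    idx <- match(sub$gene_id, g$gene_id)
    if (anyNA(idx)) return(sprintf("%s reference unknown gene ids", nm))
    inside <- GenomicRanges::start(sub) >= GenomicRanges::start(g)[idx] &
      GenomicRanges::end(sub) <= GenomicRanges::end(g)[idx]
    if (!all(inside)) return(sprintf("%s extend beyond their gene span", nm))
  }
  TRUE
})

#' Construct a GeneModels object
#' @param genes GRanges of stranded gene spans with `gene_id` (and optional
#'   `operon_id`) metadata columns
#' @param exons,utr5,utr3,introns GRanges sub-feature tracks with `gene_id`;
#'   introns are derived as span minus exons/UTRs when missing
#' @param operons GRanges of operon spans with `operon_id`
#' @return a [GeneModels-class] object
#' @export
GeneModels <- function(genes, exons = GenomicRanges::GRanges(),
                       utr5 = GenomicRanges::GRanges(),
                       utr3 = GenomicRanges::GRanges(),
                       introns = NULL, operons = GenomicRanges::GRanges()) {
  if (is.null(genes$operon_id)) genes$operon_id <- NA_character_
  if (is.null(introns)) {
    introns <- .deriveIntrons(genes, exons, utr5, utr3)
  }
  new("GeneModels", genes = genes, exons = exons, utr5 = utr5, utr3 = utr3,
      introns = introns, operons = operons)
}

## introns = gene span minus exons and UTRs, per gene
.deriveIntrons <- function(genes, exons, utr5, utr3) {
  sub <- c(GenomicRanges::granges(exons), GenomicRanges::granges(utr5),
           GenomicRanges::granges(utr3))
  ids <- c(exons$gene_id, utr5$gene_id, utr3$gene_id)
  out <- GenomicRanges::GRanges()
  if (length(sub) == 0L) return(out)
  pieces <- lapply(seq_along(genes), function(i) {
    gid <- genes$gene_id[i]
    span <- GenomicRanges::granges(genes[i])
    mine <- sub[ids == gid]
    if (length(mine) == 0L) return(NULL)
    intr <- GenomicRanges::setdiff(span, GenomicRanges::reduce(mine),
                                   ignore.strand = TRUE)
    if (length(intr) == 0L) return(NULL)
    intr$gene_id <- gid
    intr
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0L) return(out)
  do.call(c, pieces)
}

#' @describeIn GeneModels-class gene spans (GRanges)
#' @param x a GeneModels object
#' @export
geneSpans <- function(x) x@genes

#' @describeIn GeneModels-class coding exons
#' @export
codingExons <- function(x) x@exons

#' @describeIn GeneModels-class 5' untranslated regions
#' @export
fivePrimeUTRs <- function(x) x@utr5

#' @describeIn GeneModels-class 3' untranslated regions
#' @export
threePrimeUTRs <- function(x) x@utr3

#' @describeIn GeneModels-class introns
#' @export
geneIntrons <- function(x) x@introns

#' @describeIn GeneModels-class operon spans
#' @export
operonSpans <- function(x) x@operons

setMethod("show", "GeneModels", function(object) {
  cat(sprintf(
    "GeneModels: %d genes (%d in %d operons), %d exons, %d 5'UTRs, %d 3'UTRs, %d introns\n",
    length(object@genes), sum(!is.na(object@genes$operon_id)),
    length(object@operons), length(object@exons), length(object@utr5),
    length(object@utr3), length(object@introns)))
})

#' SummitRegionSet: extended, merged peak-summit regions
#'
#' Peak-calling summits (ATAC or TF ChIP) extended by a fixed flank on both
#' sides (101 bp regions for the default 50 bp flank), then merged across
#' developmental stages. The pre-merge regions are retained for auditing.
#'
#' @slot label assay/stage or TF label
#' @slot preMerge GRanges of extended, unmerged regions (width 101 except
#'   where clipped at chromosome boundaries)
#' @slot merged GRanges after merging overlapping/book-ended regions
#' @export
setClass("SummitRegionSet", representation(
  label = "character", preMerge = "GRanges", merged = "GRanges"
))

setValidity("SummitRegionSet", function(object) {
  m <- object@merged
  if (length(m) > 1L &&
      !identical(GenomicRanges::granges(m), GenomicRanges::granges(
        mergeIntervals(m))))
    return("merged slot must be merge-idempotent")
  TRUE
})

#' @describeIn SummitRegionSet-class merged summit regions
#' @param x a SummitRegionSet
#' @export
mergedRegions <- function(x) x@merged

#' @describeIn SummitRegionSet-class pre-merge extended regions
#' @export
preMergeRegions <- function(x) x@preMerge

#' @describeIn SummitRegionSet-class set label
#' @export
regionLabel <- function(x) x@label

setMethod("show", "SummitRegionSet", function(object) {
  cat(sprintf("SummitRegionSet '%s': %d summits -> %d merged regions (%.0f bp)\n",
              object@label, length(object@preMerge), length(object@merged),
              sum(GenomicRanges::width(object@merged))))
})
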