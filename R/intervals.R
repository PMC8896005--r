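#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<- DataFrame
#' @importFrom GenomeInfoDb seqnames seqlengths seqlengths<- seqlevels
#'   seqlevels<- keepSeqlevels
NULL

#' Merge an interval set
#'
#' Unions overlapping and book-ended (end == next start) intervals per
#' chromosome, the default semantics of BEDTools merge. Strand and metadata
#' are discarded; the result covers exactly the same bases and the operation
#' is idempotent.
#'
#' @param x a GRanges
#' @return a sorted, strand-free GRanges with no two ranges overlapping or
#'   abutting on the same chromosome
#' @examples
#' gr <- GenomicRanges::GRanges("chrI", IRanges::IRanges(c(1, 11), c(10, 20)))
#' mergeIntervals(gr)  # one range 1-20
#' @export
mergeIntervals <- function(x) {
  stopifnot(is(x, "GRanges"))
  sort(reduce(granges(x), ignore.strand = TRUE, min.gapwidth = 1L))
}

#' Total bases covered by an interval set
#'
#' @param x a GRanges (merged internally so overlaps are not double-counted)
#' @return numeric, number of covered bases
#' @export
totalBp <- function(x) sum(as.numeric(width(mergeIntervals(x))))

#' Motif hits completely residing within TE intervals
#'
#' Keeps exactly the hits whose interval is a subset of some TE interval
#' (strand ignored); a hit overlapping a TE boundary is excluded. Each
#' retained hit is annotated with the covering TE's type, family and repeat
#' class. When a hit lies inside several (overlapping or abutting) TE
#' records, the covering TE is the longest one, ties broken by
#' lexicographically smallest type name; such hits are flagged
#' `te_ambiguous`.
#'
#' @param hits GRanges of motif hits (any metadata preserved)
#' @param tes GRanges of TE annotations with metadata columns `te_type`,
#'   `te_family` (and optionally `repeat_class`); the un-merged track, so
#'   type labels stay unambiguous
#' @return subset of `hits` with added columns `te_type`, `te_family`,
#'   `te_class`, `te_ambiguous`
#' @export
containedHits <- function(hits, tes) {
  stopifnot(is(hits, "GRanges"), is(tes, "GRanges"))
  if (length(hits) == 0L || length(tes) == 0L) {
    out <- hits[integer(0)]
    mcols(out)$te_type <- character(0)
    mcols(out)$te_family <- character(0)
    mcols(out)$te_class <- character(0)
    mcols(out)$te_ambiguous <- logical(0)
    return(out)
  }
  if (is.null(tes$te_type)) .stopf("TE track must carry a te_type column")
  ov <- findOverlaps(hits, tes, type = "within", ignore.strand = TRUE)
  if (length(ov) == 0L) return(containedHits(hits[integer(0)], tes))
  qh <- queryHits(ov); sh <- subjectHits(ov)
  ## pick covering TE per hit: longest, then lexicographic type
  wid <- width(tes)[sh]
  typ <- as.character(tes$te_type)[sh]
  ord <- order(qh, -wid, typ, sh)
  qh <- qh[ord]; sh <- sh[ord]
  first <- !duplicated(qh)
  ambiguous <- qh[first] %in% qh[duplicated(qh)]
  keep <- qh[first]
  cover <- sh[first]
  out <- hits[keep]
  mcols(out)$te_type <- as.character(tes$te_type)[cover]
  fam <- if (!is.null(tes$te_family)) as.character(tes$te_family)[cover]
         else rep(NA_character_, length(cover))
  cls <- if (!is.null(tes$repeat_class)) as.character(tes$repeat_class)[cover]
         else rep(NA_character_, length(cover))
  mcols(out)$te_family <- fam
  mcols(out)$te_class <- cls
  mcols(out)$te_ambiguous <- ambiguous
  out
}

#' Promoter regions upstream of genes or operons
#'
#' The promoter of a gene is the window `upstreamBp` bases upstream of its
#' start, strand-aware and clipped at chromosome boundaries (BED semantics:
#' for a + strand gene spanning `[s, e)` the promoter is
#' `[max(0, s - upstreamBp), s)`; for a - strand gene, `[e, e + upstreamBp)`
#' clipped at the chromosome length). With `exclusive = TRUE`, bases
#' overlapping coding exons, UTRs or introns of any gene are subtracted and
#' genes belonging to an operon are replaced by a single operon promoter.
#' With `exclusive = FALSE` every gene keeps its raw upstream window,
#' overlapping features included.
#'
#' @param geneModels a [GeneModels-class] object (or a stranded GRanges with
#'   `gene_id` for the simple inclusive case)
#' @param upstreamBp promoter length in bp (default 2500)
#' @param exclusive subtract overlapping exons/UTRs/introns and use operon
#'   promoters for operon genes (the genome-partition variant); default FALSE
#' @param useOperons with `exclusive = TRUE`, whether operon promoters
#'   replace member-gene promoters (default TRUE when operons are present)
#' @return GRanges of promoter intervals with columns `gene_id` (the gene or
#'   operon identifier) and `unit` ("gene" or "operon"); exclusive promoters
#'   may be split into several fragments per gene
#' @export
promoterRegions <- function(geneModels, upstreamBp = 2500, exclusive = FALSE,
                            useOperons = NULL) {
  if (is(geneModels, "GRanges")) {
    geneModels <- GeneModels(genes = geneModels)
  }
  stopifnot(is(geneModels, "GeneModels"), upstreamBp > 0)
  genes <- geneSpans(geneModels)
  if (any(strand(genes) == "*")) .stopf("unstranded gene(s): %s",
    paste(head(genes$gene_id[strand(genes) == "*"], 3), collapse = ", "))
  ops <- operonSpans(geneModels)
  if (is.null(useOperons)) useOperons <- exclusive && length(ops) > 0L

  .window <- function(gr, ids, unit) {
    if (length(gr) == 0L) {
      out <- GRanges(seqlengths = seqlengths(genes))
      out$gene_id <- character(0); out$unit <- character(0)
      return(out)
    }
    plus <- as.logical(strand(gr) == "+")
    sl <- seqlengths(gr)[as.character(seqnames(gr))]
    st <- ifelse(plus, start(gr) - upstreamBp, end(gr) + 1L)
    en <- ifelse(plus, start(gr) - 1L, end(gr) + upstreamBp)
    en <- ifelse(is.na(sl), en, pmin(en, sl))
    st <- pmax(st, 1L)
    keep <- st <= en
    out <- GRanges(seqnames(gr)[keep], IRanges(st[keep], en[keep]),
                   strand = strand(gr)[keep], seqlengths = seqlengths(gr))
    out$gene_id <- ids[keep]; out$unit <- unit
    out[width(out) > 0L]
  }

  if (useOperons) {
    solo <- genes[is.na(genes$operon_id)]
    prom <- .window(solo, solo$gene_id, "gene")
    if (length(ops) > 0L) {
      if (any(strand(ops) == "*")) .stopf("unstranded operon(s)")
      prom <- c(prom, .window(ops, ops$operon_id, "operon"))
    }
  } else {
    prom <- .window(genes, genes$gene_id, "gene")
  }

  if (exclusive) {
    feat <- reduce(c(granges(codingExons(geneModels)),
                     granges(fivePrimeUTRs(geneModels)),
                     granges(threePrimeUTRs(geneModels)),
                     granges(geneIntrons(geneModels))), ignore.strand = TRUE)
    if (length(feat) > 0L) {
      ## intersect every window with the feature-free complement in one
      ## overlap query instead of one setdiff per window
      sl <- seqlengths(genes)
      if (anyNA(sl))
        sl[is.na(sl)] <- vapply(names(sl)[is.na(sl)], function(ch)
          max(end(prom)[seqnames(prom) == ch],
              end(feat)[seqnames(feat) == ch], 1L), numeric(1))
      genomeGr <- GRanges(names(sl), IRanges(1L, as.integer(sl)),
                          seqlengths = seqlengths(genes))
      nonFeat <- setdiff(genomeGr, feat, ignore.strand = TRUE)
      ov <- findOverlaps(prom, nonFeat, ignore.strand = TRUE)
      q <- queryHits(ov); s <- subjectHits(ov)
      frag <- GRanges(seqnames(prom)[q],
                      IRanges(pmax(start(prom)[q], start(nonFeat)[s]),
                              pmin(end(prom)[q], end(nonFeat)[s])),
                      strand = strand(prom)[q],
                      seqlengths = seqlengths(genes))
      frag$gene_id <- prom$gene_id[q]
      frag$unit <- prom$unit[q]
      prom <- frag
    }
  }
  sort(prom, ignore.strand = TRUE)
}

#' Partition the genome into annotation classes and tabulate TE coverage
#'
#' Emits one row per feature class -- coding exons, 5'UTRs, 3'UTRs, introns,
#' promoters (exclusive variant), operon promoters, distal intergenic, and
#' the whole genome -- with the class's total bp and the bp of that class
#' covered by TEs. Distal intergenic is the genomic space outside every
#' other class; the remaining classes may overlap one another, so summed
#' class bp can exceed the genome size.
#'
#' @param seqlen named integer of chromosome lengths
#' @param geneModels a [GeneModels-class] object
#' @param tes GRanges of TE annotations
#' @param upstreamBp promoter window length (default 2500)
#' @return data.frame with columns `class`, `class_bp`, `te_bp`
#' @export
featurePartition <- function(seqlen, geneModels, tes, upstreamBp = 2500) {
  if (is.null(names(seqlen)) || anyNA(seqlen))
    .stopf("named chromosome lengths are required")
  genomeGr <- GRanges(names(seqlen), IRanges(1L, as.integer(seqlen)),
                      seqlengths = seqlen)
  teM <- mergeIntervals(tes)
  prom <- promoterRegions(geneModels, upstreamBp = upstreamBp,
                          exclusive = TRUE, useOperons = TRUE)
  classes <- list(
    coding_exons = granges(codingExons(geneModels)),
    utr5 = granges(fivePrimeUTRs(geneModels)),
    utr3 = granges(threePrimeUTRs(geneModels)),
    introns = granges(geneIntrons(geneModels)),
    promoters = granges(prom[prom$unit == "gene"]),
    operon_promoters = granges(prom[prom$unit == "operon"])
  )
  classes <- lapply(classes, function(g) {
    seqlevels(g) <- names(seqlen); seqlengths(g) <- seqlen; mergeIntervals(g)
  })
  covered <- mergeIntervals(do.call(c, unname(classes)))
  classes$distal_intergenic <- setdiff(genomeGr, covered, ignore.strand = TRUE)
  classes$whole_genome <- genomeGr
  rows <- lapply(names(classes), function(nm) {
    cls <- classes[[nm]]
    data.frame(class = nm,
               class_bp = sum(as.numeric(width(cls))),
               te_bp = sum(as.numeric(width(
                 intersect(cls, teM, ignore.strand = TRUE)))))
  })
  do.call(rbind, rows)
}
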