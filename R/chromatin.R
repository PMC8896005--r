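#' Build summit regions from peak summits
#'
#' Extends each single-base summit by `flank` bp in both directions
#' (yielding 101-bp regions at the default flank of 50), clipped at
#' chromosome boundaries, then merges regions across all supplied stage
#' sets. Summits lying off their chromosome are rejected with a notice.
#'
#' @param summits GRanges of width-1 summit positions, or a list of such
#'   objects (one per developmental stage)
#' @param label label for the set (assay + stage, or TF name)
#' @param flank extension in bp on each side (default 50)
#' @param seqlen named chromosome lengths, needed for boundary clipping
#'   when absent from the input
#' @return a [SummitRegionSet-class]
#' @export
buildSummitRegions <- function(summits, label = "summits", flank = 50,
                               seqlen = NULL) {
  if (is(summits, "GRanges")) summits <- list(summits)
  all <- suppressWarnings(do.call(c, unname(lapply(summits, granges))))
  if (!is.null(seqlen)) {
    seqlevels(all) <- union(names(seqlen), seqlevels(all))
    ## off-chromosome summits are rejected just below, so the transient
    ## out-of-bound state is expected here
    suppressWarnings(seqlengths(all)[names(seqlen)] <- seqlen)
  }
  sl <- seqlengths(all)
  if (length(all) > 0L) {
    if (any(width(all) != 1L)) .stopf("summits must be single-base positions")
    off <- !is.na(sl[as.character(seqnames(all))]) &
      (start(all) < 1L | start(all) > sl[as.character(seqnames(all))])
    if (any(off)) {
      .msgf("%d summit(s) off chromosome rejected", sum(off))
      all <- all[!off]
    }
  }
  pre <- trim(suppressWarnings(resize(all, width = 2L * flank + 1L, fix = "center")))
  new("SummitRegionSet", label = label, preMerge = sort(pre),
      merged = mergeIntervals(pre))
}

.asMerged <- function(x) {
  if (is(x, "SummitRegionSet")) mergedRegions(x) else mergeIntervals(x)
}

#' Fraction of accessible motif instances located within TEs
#'
#' Per motif: the denominator is the number of genome-wide hits completely
#' residing within merged accessible (ATAC summit) regions; the numerator
#' is the subset of those also completely residing within TEs. Gate flags
#' record whether the motif clears the denominator floor (strictly more
#' than `minSites` accessible instances) and the percentage floor (strictly
#' more than `minPct` percent within TEs). All motifs are returned with
#' their flags so census claims remain checkable.
#'
#' @param hits GRanges of genome-wide scan hits (column `name`)
#' @param atac a [SummitRegionSet-class] (or GRanges) of accessible regions
#' @param tes GRanges TE track
#' @param minSites accessible-instance floor (default 3000)
#' @param minPct percent floor (default 10)
#' @return data.frame: `name`, `n_accessible`, `n_accessible_te`,
#'   `percent`, `pass_floor`, `pass_percent`, `passes`
#' @export
accessibleMotifFractions <- function(hits, atac, tes, minSites = 3000,
                                     minPct = 10) {
  open <- .asMerged(atac)
  motifs <- sort(unique(as.character(hits$name)))
  acc <- hits[overlapsAny(hits, open, type = "within", ignore.strand = TRUE)]
  accTe <- containedHits(acc, tes)
  den <- table(factor(acc$name, levels = motifs))
  num <- table(factor(accTe$name, levels = motifs))
  out <- data.frame(name = motifs,
                    n_accessible = as.integer(den),
                    n_accessible_te = as.integer(num))
  out$percent <- ifelse(out$n_accessible > 0,
                        100 * out$n_accessible_te / out$n_accessible, 0)
  out$pass_floor <- out$n_accessible > minSites
  out$pass_percent <- out$percent > minPct
  out$passes <- out$pass_floor & out$pass_percent
  out
}

#' Fraction of TF-bound regions containing TE-provided cognate motifs
#'
#' For each TF (cognate motif paired with that TF's merged ChIP summit
#' regions): the denominator is the number of bound regions containing at
#' least one cognate motif hit (full containment); the numerator is the
#' number of bound regions whose contained cognate hit is TE-contained. A
#' region with several hits counts once, and is TE-derived if any contained
#' hit is TE-contained. TFs are gated on having strictly more than
#' `minRegions` bound regions and strictly more than `minPct` percent
#' TE-derived bound-motif regions. With `unit = "instances"` the counts are
#' motif instances within bound regions instead of regions.
#'
#' @param hits GRanges of genome-wide scan hits (`name` = motif id)
#' @param chipSets named list of [SummitRegionSet-class] (or GRanges),
#'   names matching motif ids (cognate pairing)
#' @param tes GRanges TE track
#' @param minRegions bound-region floor (default 500)
#' @param minPct percent floor (default 5)
#' @param unit "regions" (default) or "instances"
#' @return data.frame: `name`, `n_bound_regions`, `n_bound_with_motif`,
#'   `n_bound_te`, `percent`, `pass_floor`, `pass_percent`, `passes`
#' @export
boundMotifFractions <- function(hits, chipSets, tes, minRegions = 500,
                                minPct = 5, unit = c("regions", "instances")) {
  unit <- match.arg(unit)
  teHits <- containedHits(hits, tes)
  rows <- lapply(sort(names(chipSets)), function(m) {
    bound <- .asMerged(chipSets[[m]])
    mine <- hits[hits$name == m]
    mineTe <- teHits[teHits$name == m]
    ovAll <- findOverlaps(mine, bound, type = "within", ignore.strand = TRUE)
    ovTe <- findOverlaps(mineTe, bound, type = "within", ignore.strand = TRUE)
    if (unit == "regions") {
      den <- length(unique(subjectHits(ovAll)))
      num <- length(unique(subjectHits(ovTe)))
    } else {
      den <- length(unique(queryHits(ovAll)))
      num <- length(unique(queryHits(ovTe)))
    }
    data.frame(name = m, n_bound_regions = length(bound),
               n_bound_with_motif = den, n_bound_te = num)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    .msgf("no TF with ChIP data: nothing to compute")
    return(data.frame(name = character(0), n_bound_regions = integer(0),
                      n_bound_with_motif = integer(0),
                      n_bound_te = integer(0), percent = numeric(0),
                      pass_floor = logical(0), pass_percent = logical(0),
                      passes = logical(0)))
  }
  out$percent <- ifelse(out$n_bound_with_motif > 0,
                        100 * out$n_bound_te / out$n_bound_with_motif, 0)
  out$pass_floor <- out$n_bound_regions > minRegions
  out$pass_percent <- out$percent > minPct
  out$passes <- out$pass_floor & out$pass_percent
  out
}

#' Top TE-type contributors of TE-contained motif instances
#'
#' Ranks, per motif, the TE types contributing the greatest numbers of
#' (accessible or bound) TE-contained instances; descending by count, ties
#' broken lexicographically by type name.
#'
#' @param teHits GRanges of TE-contained hits (columns `name`, `te_type`),
#'   or a data.frame with those columns
#' @param k number of top types per motif (default 5)
#' @return data.frame `name`, `te_type`, `count`, `rank`
#' @export
topTeContributors <- function(teHits, k = 5) {
  df <- if (is(teHits, "GRanges"))
    data.frame(name = as.character(teHits$name),
               te_type = as.character(teHits$te_type))
  else teHits[, c("name", "te_type")]
  if (nrow(df) == 0L)
    return(data.frame(name = character(0), te_type = character(0),
                      count = integer(0), rank = integer(0)))
  tab <- as.data.frame(table(df$name, df$te_type),
                       stringsAsFactors = FALSE)
  names(tab) <- c("name", "te_type", "count")
  tab <- tab[tab$count > 0, ]
  tab <- tab[order(tab$name, -tab$count, tab$te_type), ]
  pieces <- lapply(split(tab, tab$name), function(x) {
    x <- head(x, k)
    x$rank <- seq_len(nrow(x))
    x
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Thin wrapper around the exact conditional test with explicit handling of
#' degenerate margins (an all-zero row or column gives p = 1 with a flag).
#' @param tab 2x2 integer matrix
#' @return list with `p`, `degenerate`
#' @export
teFisherTest <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p = 1, degenerate = TRUE))
  list(p = fisher.test(tab, alternative = "two.sided")$p.value,
       degenerate = FALSE)
}

#' Association between TE-provided motifs and chromatin accessibility
#'
#' Classifies each of a TF's bound regions by whether it contains a
#' TE-provided cognate motif (full containment) and whether it overlaps a
#' merged accessible region (any overlap), and applies a two-sided Fisher's
#' exact test to the resulting 2x2 table.
#'
#' @param chipRegions a [SummitRegionSet-class] (or GRanges) of the TF's
#'   bound regions
#' @param atacRegions a [SummitRegionSet-class] (or GRanges) of accessible
#'   regions
#' @param teHits GRanges of the TF's TE-contained cognate motif hits
#' @return list with `table` (2x2: rows TE motif yes/no, columns accessible
#'   yes/no), `p` and `degenerate`
#' @export
accessibilityFisher <- function(chipRegions, atacRegions, teHits) {
  bound <- .asMerged(chipRegions)
  open <- .asMerged(atacRegions)
  within <- findOverlaps(teHits, bound, type = "within",
                         ignore.strand = TRUE)
  hasTe <- seq_along(bound) %in% subjectHits(within)
  isOpen <- overlapsAny(bound, open, ignore.strand = TRUE)
  tab <- matrix(c(sum(hasTe & isOpen), sum(hasTe & !isOpen),
                  sum(!hasTe & isOpen), sum(!hasTe & !isOpen)),
                nrow = 2, byrow = TRUE,
                dimnames = list(te_motif = c("yes", "no"),
                                accessible = c("yes", "no")))
  res <- teFisherTest(tab)
  list(table = tab, p = res$p, degenerate = res$degenerate)
}
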