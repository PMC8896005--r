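#' TE coverage percentage of a feature class
#'
#' The share of a feature class covered by TEs, as printed in coverage
#' reports: `100 * te_bp / class_bp`.
#' @param teBp bases of the class covered by TEs
#' @param classBp total bases of the class
#' @return percentage (0-100)
#' @export
percentTeCoverage <- function(teBp, classBp) {
  if (any(classBp <= 0)) .stopf("class has zero length")
  100 * teBp / classBp
}

#' Fold change between TE-genome and non-TE-genome shares
#'
#' Given the percentage of the TE genome and of the non-TE genome occupied
#' by a feature class, the fold change is their ratio; values below 1 are
#' reported as an x-fold depletion (the reciprocal).
#' @param shareTe percent of TE space occupied by the class
#' @param shareNonTe percent of non-TE space occupied by the class
#' @return list with `fold` (raw ratio), `display` (>= 1 reciprocal form)
#'   and `direction` ("enrichment" or "depletion")
#' @export
foldVsNonTe <- function(shareTe, shareNonTe) {
  if (shareNonTe <= 0 || shareTe <= 0)
    return(list(fold = NA_real_, display = NA_real_,
                direction = if (shareTe == 0) "infinite_depletion"
                            else "infinite_enrichment"))
  fold <- shareTe / shareNonTe
  if (fold >= 1) list(fold = fold, display = fold, direction = "enrichment")
  else list(fold = fold, display = 1 / fold, direction = "depletion")
}

#' TE coverage table across feature classes
#'
#' For each feature class of a genome partition: the percentage of the
#' class covered by TEs, the class's share of the TE genome and of the
#' non-TE genome, and the fold enrichment (or depletion) of the class
#' within TEs relative to outside TEs.
#'
#' @param partition data.frame from [featurePartition()] (columns `class`,
#'   `class_bp`, `te_bp`), including a `whole_genome` row
#' @return data.frame with columns `class`, `class_bp`, `te_bp`,
#'   `percent_te`, `share_of_te`, `share_of_nonte`, `fold`, `fold_display`,
#'   `direction`
#' @export
coverageTable <- function(partition) {
  need <- c("class", "class_bp", "te_bp")
  if (!all(need %in% names(partition))) .stopf("partition lacks %s",
    paste(setdiff(need, names(partition)), collapse = ", "))
  wg <- partition[partition$class == "whole_genome", ]
  if (nrow(wg) != 1L) .stopf("partition must contain one whole_genome row")
  genomeBp <- wg$class_bp; teBp <- wg$te_bp
  nonTeBp <- genomeBp - teBp
  out <- partition
  zero <- out$class_bp <= 0
  out$percent_te <- ifelse(zero, NA_real_,
                           100 * out$te_bp / out$class_bp)
  out$share_of_te <- if (teBp > 0) 100 * out$te_bp / teBp else NA_real_
  out$share_of_nonte <- if (nonTeBp > 0)
    100 * (out$class_bp - out$te_bp) / nonTeBp else NA_real_
  fc <- Map(foldVsNonTe, out$share_of_te, out$share_of_nonte)
  out$fold <- vapply(fc, `[[`, numeric(1), "fold")
  out$fold_display <- vapply(fc, `[[`, numeric(1), "display")
  out$direction <- vapply(fc, `[[`, character(1), "direction")
  out$flag_zero_class <- zero
  out
}

#' Per-(motif, TE-type) fold enrichment with a binomial null
#'
#' For each motif and each TE type: the motif's genome-wide instance count,
#' the count of instances completely residing within that TE type, the fold
#' enrichment -- the proportion of the motif's instances in the type
#' divided by the type's share of the genome -- and the one-sided binomial
#' tail probability `P(X >= n_in | n_total, p0 = te_bp / genome_bp)`. Each
#' instance is treated as an independent Bernoulli trial with success
#' probability equal to the type's genome share. TE bp per type is computed
#' on the merged per-type track so overlapping fragments are not double
#' counted.
#'
#' @param hits GRanges of genome-wide scan hits (column `name` = motif id;
#'   `tf_name` optional)
#' @param tes GRanges TE track with `te_type` / `te_family`
#' @param seqlen named chromosome lengths (defines genome bp)
#' @return data.frame with one row per (motif, TE type) present: columns
#'   `name`, `tf_name`, `te_type`, `te_family`, `n_total`, `n_in`, `te_bp`,
#'   `genome_bp`, `fold`, `p`
#' @export
motifTeEnrichment <- function(hits, tes, seqlen) {
  genomeBp <- sum(as.numeric(seqlen))
  if (genomeBp <= 0) .stopf("genome length must be positive")
  if (length(hits) == 0L) {
    .msgf("no motif hits: no enrichment records")
    return(data.frame(name = character(0), tf_name = character(0),
                      te_type = character(0), te_family = character(0),
                      n_total = integer(0), n_in = integer(0),
                      te_bp = numeric(0), genome_bp = numeric(0),
                      fold = numeric(0), p = numeric(0)))
  }
  types <- sort(unique(as.character(tes$te_type)))
  typeBp <- vapply(types, function(tt)
    totalBp(tes[tes$te_type == tt]), numeric(1))
  typeFam <- vapply(types, function(tt) {
    fams <- unique(as.character(tes$te_family[tes$te_type == tt]))
    fams[1]
  }, character(1))
  keepTypes <- types[typeBp > 0]

  inTe <- containedHits(hits, tes)
  motifs <- sort(unique(hits$name))
  tfOf <- if (!is.null(hits$tf_name))
    setNames(as.character(hits$tf_name), hits$name)[motifs]
  else setNames(motifs, motifs)
  nTotal <- table(factor(hits$name, levels = motifs))
  nIn <- table(factor(inTe$name, levels = motifs),
               factor(inTe$te_type, levels = keepTypes))

  emptyRec <- data.frame(name = character(0), tf_name = character(0),
                         te_type = character(0), te_family = character(0),
                         n_total = integer(0), n_in = integer(0),
                         te_bp = numeric(0), genome_bp = numeric(0),
                         fold = numeric(0), p = numeric(0))
  if (length(keepTypes) == 0L) {
    .msgf("no TE types with positive coverage: no enrichment records")
    return(emptyRec)
  }
  rows <- expand.grid(name = motifs, te_type = keepTypes,
                      stringsAsFactors = FALSE)
  rows <- rows[order(rows$name, rows$te_type), ]
  rows$tf_name <- unname(tfOf[rows$name])
  rows$te_family <- unname(typeFam[rows$te_type])
  rows$n_total <- as.integer(nTotal[rows$name])
  rows$n_in <- as.integer(nIn[cbind(rows$name, rows$te_type)])
  rows$te_bp <- unname(typeBp[rows$te_type])
  rows$genome_bp <- genomeBp
  p0 <- rows$te_bp / genomeBp
  rows$fold <- (rows$n_in / rows$n_total) / p0
  rows$p <- pbinom(rows$n_in - 1L, rows$n_total, p0, lower.tail = FALSE)
  omit <- rows$n_total == 0
  if (any(omit)) {
    .msgf("%d motif(s) with zero genomic instances omitted",
          length(unique(rows$name[omit])))
    rows <- rows[!omit, ]
  }
  rownames(rows) <- NULL
  rows[, c("name", "tf_name", "te_type", "te_family", "n_total", "n_in",
           "te_bp", "genome_bp", "fold", "p")]
}

#' Filter enrichment records through the gate cascade
#'
#' Keeps (motif, TE type) records whose TE type covers more than `minTeBp`
#' of the genome, whose fold enrichment exceeds `minFold`, and whose
#' binomial p-value is below `maxP`. All three thresholds are strict.
#'
#' @param records data.frame from [motifTeEnrichment()]
#' @param minTeBp minimum genome coverage of the TE type in bp (default
#'   20000)
#' @param minFold minimum fold enrichment (default 20)
#' @param maxP maximum binomial p (default 1e-12)
#' @param returnAll return all records with a `passes_filters` flag instead
#'   of the passing subset
#' @return filtered data.frame (or flagged full set)
#' @export
filterEnriched <- function(records, minTeBp = 20000, minFold = 20,
                           maxP = 1e-12, returnAll = FALSE) {
  pass <- records$te_bp > minTeBp & records$fold > minFold & records$p < maxP
  pass[is.na(pass)] <- FALSE
  if (returnAll) {
    records$passes_filters <- pass
    return(records)
  }
  out <- records[pass, ]
  rownames(out) <- NULL
  out
}

#' Percentage of a motif's instances inside chosen TE types
#'
#' `100 * (sum of in-type instance counts over the chosen types) /
#' n_total`, the per-motif quantity reported next to the enrichment
#' heatmap.
#'
#' @param records data.frame from [motifTeEnrichment()]
#' @param motif motif id
#' @param teTypes TE types to sum over (default: all types in `records`)
#' @return percentage (0-100)
#' @export
motifPercentInTe <- function(records, motif, teTypes = NULL) {
  sub <- records[records$name == motif, ]
  if (nrow(sub) == 0L || sub$n_total[1] == 0)
    .stopf("motif %s has no genomic instances", motif)
  nTotal <- sub$n_total[1]
  if (!is.null(teTypes)) sub <- sub[sub$te_type %in% teTypes, ]
  100 * sum(sub$n_in) / nTotal
}

#' Genes with TE-contained motif hits in their promoters
#'
#' A gene counts for a motif when at least one TE-contained hit of that
#' motif lies fully within the gene's promoter window; a hit falling in two
#' genes' overlapping windows counts both genes (genes are counted, not
#' hits). Also returns the deduplicated union of genes across motifs.
#'
#' @param promoters GRanges of (inclusive) promoter windows with `gene_id`
#' @param teHits GRanges of TE-contained hits (from [containedHits()];
#'   columns `name`, and `te_type`/`te_family` if present are carried
#'   through)
#' @return list with `pairs` (data.frame motif/gene/hit detail),
#'   `perMotif` (named list of gene-id vectors) and `unionGenes`
#'   (character vector)
#' @export
genesWithTeMotifs <- function(promoters, teHits) {
  ov <- findOverlaps(teHits, promoters, type = "within",
                     ignore.strand = TRUE)
  if (length(ov) == 0L) {
    return(list(pairs = data.frame(name = character(0),
                                   gene_id = character(0),
                                   chrom = character(0), start = integer(0),
                                   end = integer(0),
                                   te_type = character(0),
                                   te_family = character(0)),
                perMotif = list(), unionGenes = character(0)))
  }
  h <- teHits[queryHits(ov)]
  pairs <- data.frame(
    name = as.character(h$name),
    gene_id = as.character(promoters$gene_id[subjectHits(ov)]),
    chrom = as.character(seqnames(h)),
    start = start(h), end = end(h),
    te_type = if (!is.null(h$te_type)) as.character(h$te_type)
              else NA_character_,
    te_family = if (!is.null(h$te_family)) as.character(h$te_family)
                else NA_character_,
    stringsAsFactors = FALSE)
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs$name, pairs$gene_id, pairs$chrom, pairs$start), ]
  rownames(pairs) <- NULL
  perMotif <- lapply(split(pairs$gene_id, pairs$name), function(g)
    sort(unique(g)))
  list(pairs = pairs, perMotif = perMotif,
       unionGenes = sort(unique(pairs$gene_id)))
}
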