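#' Per-motif gene sets with promoter TE-provided motifs, for one species
#'
#' Convenience wrapper composing the per-species steps: inclusive promoter
#' windows from the species' gene models, TE containment of the species'
#' scan hits, and gene counting via [genesWithTeMotifs()].
#'
#' @param hits GRanges of the species' genome-wide scan hits
#' @param tes GRanges of the species' TE track
#' @param geneModels the species' [GeneModels-class]
#' @param upstreamBp promoter window (default 2500)
#' @return as [genesWithTeMotifs()]
#' @export
promoterTeMotifGenes <- function(hits, tes, geneModels, upstreamBp = 2500) {
  prom <- promoterRegions(geneModels, upstreamBp = upstreamBp,
                          exclusive = FALSE)
  genesWithTeMotifs(prom, containedHits(hits, tes))
}

#' Hypergeometric test for shared orthologs with promoter TE motifs
#'
#' Given the set of species-A genes and species-B genes carrying a
#' promoter TE-provided motif, restricted to a strict one-to-one ortholog
#' map of N pairs: K = A-side genes in the map, n = B-side genes in the
#' map, k = pairs present on both sides. The upper-tail hypergeometric
#' probability P(X >= k | N, K, n) measures whether the sharing exceeds
#' chance. Gene ids absent from the map are dropped with a notice.
#'
#' @param setA character vector of species-A gene ids with the feature
#' @param setB character vector of species-B gene ids with the feature
#' @param map data.frame from [readOrthologMap()] (columns `idA`, `idB`)
#' @return list with `N`, `K`, `n`, `k`, `p`, `stars` (significance at
#'   0.05 / 0.01 / 1e-05) and `sharedPairs` (data.frame idA, idB)
#' @export
sharedOrthologTest <- function(setA, setB, map) {
  if (nrow(map) == 0L) .stopf("empty ortholog map")
  if (anyDuplicated(map$idA) || anyDuplicated(map$idB))
    .stopf("ortholog map is not one-to-one")
  dropA <- setdiff(setA, map$idA)
  dropB <- setdiff(setB, map$idB)
  if (length(dropA) + length(dropB) > 0)
    .msgf("%d A-side and %d B-side gene id(s) missing from the map dropped",
          length(dropA), length(dropB))
  setA <- intersect(setA, map$idA)
  setB <- intersect(setB, map$idB)
  N <- nrow(map)
  K <- length(setA)
  n <- length(setB)
  inA <- map$idA %in% setA
  inB <- map$idB %in% setB
  shared <- map[inA & inB, , drop = FALSE]
  k <- nrow(shared)
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  stars <- if (p < 1e-5) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else ""
  list(N = N, K = K, n = n, k = k, p = p, stars = stars,
       sharedPairs = shared)
}

#' Default TE-family normalization table
#'
#' Maps annotation-specific repeat family strings onto shared superfamily
#' keys so that family labels can be compared across species whose TE
#' annotations use different naming conventions (e.g. all Tc1/mariner
#' spellings collapse to one key). Editable: pass a modified copy to
#' [familySimilarity()].
#'
#' @return named character vector (raw label -> normalized key)
#' @export
familyNormalizationTable <- function() {
  c("Tc1/mariner" = "Tc1/mariner", "Tc1-Mariner" = "Tc1/mariner",
    "TcMar" = "Tc1/mariner", "TcMar-Tc1" = "Tc1/mariner",
    "TcMar-Mariner" = "Tc1/mariner", "Mariner/Tc1" = "Tc1/mariner",
    "Tc1" = "Tc1/mariner", "Mariner" = "Tc1/mariner",
    "Helitron" = "Helitron", "RC/Helitron" = "Helitron",
    "RC-Helitron" = "Helitron",
    "MULE-MuDR" = "MULE-MuDR", "MuDR" = "MULE-MuDR",
    "hAT" = "hAT", "hAT-Ac" = "hAT",
    "CR1" = "CR1", "LINE/CR1" = "CR1",
    "RTE" = "RTE", "LINE/RTE" = "RTE",
    "Gypsy" = "Gypsy", "LTR/Gypsy" = "Gypsy",
    "Pao" = "Pao", "LTR/Pao" = "Pao")
}

.normalizeFamily <- function(labels, table) {
  out <- unname(table[labels])
  unknown <- is.na(out) & !is.na(labels)
  if (any(unknown)) {
    warning(sprintf("unknown TE family label(s) %s: using raw string equality",
                    paste(unique(labels[unknown]), collapse = ", ")),
            call. = FALSE)
    out[unknown] <- labels[unknown]
  }
  out
}

#' Classify shared ortholog pairs by TE-family similarity
#'
#' A shared pair is "similar" when any (normalized) family label of the
#' motif-containing promoter TEs on its A side equals any such label on its
#' B side; otherwise "different".
#'
#' @param sharedPairs data.frame with columns `idA`, `idB`
#' @param famA named list: A-side gene id -> character vector of promoter
#'   TE family labels (motif-containing TEs only)
#' @param famB named list: B-side equivalent
#' @param normalization named character map as from
#'   [familyNormalizationTable()]
#' @return data.frame `idA`, `idB`, `similar` plus summary attribute-free
#'   columns `families_a`, `families_b`
#' @export
familySimilarity <- function(sharedPairs, famA, famB,
                             normalization = familyNormalizationTable()) {
  if (nrow(sharedPairs) == 0L)
    return(data.frame(idA = character(0), idB = character(0),
                      similar = logical(0), families_a = character(0),
                      families_b = character(0)))
  sim <- logical(nrow(sharedPairs))
  fa <- character(nrow(sharedPairs)); fb <- character(nrow(sharedPairs))
  for (i in seq_len(nrow(sharedPairs))) {
    a <- .normalizeFamily(unique(famA[[sharedPairs$idA[i]]]), normalization)
    b <- .normalizeFamily(unique(famB[[sharedPairs$idB[i]]]), normalization)
    sim[i] <- length(intersect(a, b)) > 0
    fa[i] <- paste(sort(a), collapse = ",")
    fb[i] <- paste(sort(b), collapse = ",")
  }
  data.frame(idA = sharedPairs$idA, idB = sharedPairs$idB, similar = sim,
             families_a = fa, families_b = fb, stringsAsFactors = FALSE)
}

#' Shared orthologs whose A-side promoter TE motif is TF-bound
#'
#' Counts shared ortholog pairs for which at least one A-side promoter
#' TE-contained motif hit lies completely within a cognate TF-bound region.
#'
#' @param sharedPairs data.frame with column `idA`
#' @param hitPairs data.frame from [genesWithTeMotifs()]`$pairs` for
#'   species A, restricted to the motif of interest (columns `gene_id`,
#'   `chrom`, `start`, `end`)
#' @param chipRegions a [SummitRegionSet-class] (or GRanges) of the
#'   cognate TF's bound regions in species A; NULL flags the count as
#'   undefined
#' @return list with `count` (integer or NA), `boundGenes` (A-side ids),
#'   `defined`
#' @export
boundShared <- function(sharedPairs, hitPairs, chipRegions) {
  if (is.null(chipRegions))
    return(list(count = NA_integer_, boundGenes = character(0),
                defined = FALSE))
  bound <- .asMerged(chipRegions)
  mine <- hitPairs[hitPairs$gene_id %in% sharedPairs$idA, , drop = FALSE]
  if (nrow(mine) == 0L)
    return(list(count = 0L, boundGenes = character(0), defined = TRUE))
  gr <- GRanges(mine$chrom, IRanges(mine$start, mine$end))
  inBound <- overlapsAny(gr, bound, type = "within", ignore.strand = TRUE)
  genes <- sort(unique(mine$gene_id[inBound]))
  list(count = length(genes), boundGenes = genes, defined = TRUE)
}
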