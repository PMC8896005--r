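#' Run configuration for the end-to-end analysis
#'
#' Collects every threshold of the analysis with the study's printed values
#' as defaults. All gates are overridable so sensitivity analyses are
#' possible without code edits; the values used are recorded verbatim in
#' the run manifest.
#'
#' @param upstreamBp promoter window (default 2500)
#' @param pThreshold motif-scan p-value threshold (default 1e-4)
#' @param minTeBp,minFold,maxP enrichment gate cascade (defaults 20000 bp,
#'   20-fold, 1e-12)
#' @param accessMinSites,accessMinPct accessibility gates (defaults 3000
#'   sites, 10 percent)
#' @param boundMinRegions,boundMinPct binding gates (defaults 500 regions,
#'   5 percent)
#' @param sigLevels significance levels for ortholog-sharing stars
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic)
#' @return list of class `RunConfig`
#' @export
runConfig <- function(upstreamBp = 2500, pThreshold = 1e-4,
                      minTeBp = 20000, minFold = 20, maxP = 1e-12,
                      accessMinSites = 3000, accessMinPct = 10,
                      boundMinRegions = 500, boundMinPct = 5,
                      sigLevels = c(0.05, 0.01, 1e-5), seed = 1L) {
  cfg <- list(upstreamBp = upstreamBp, pThreshold = pThreshold,
              minTeBp = minTeBp, minFold = minFold, maxP = maxP,
              accessMinSites = accessMinSites, accessMinPct = accessMinPct,
              boundMinRegions = boundMinRegions, boundMinPct = boundMinPct,
              sigLevels = sigLevels, seed = seed)
  if (any(unlist(cfg[1:9]) <= 0)) .stopf("all thresholds must be positive")
  structure(cfg, class = "RunConfig")
}

.checkChromNames <- function(seqlen, gr, what) {
  bad <- setdiff(as.character(unique(seqnames(gr))), names(seqlen))
  if (length(bad))
    .stopf("chromosome name mismatch in %s: %s not in genome", what,
           paste(bad, collapse = ", "))
}

#' Run the full TE-motif analysis pipeline on an input bundle
#'
#' Executes scan -> TE containment -> feature-partition coverage table ->
#' per-(motif, TE type) enrichment with the filter cascade and promoter
#' gene lists -> accessibility and binding fraction analyses -> (when a
#' second species is present) the cross-species ortholog sharing test, and
#' writes one TSV/BED per stage plus a machine-readable manifest. The run
#' is deterministic: rerunning on the same inputs gives byte-identical
#' outputs.
#'
#' @param inputDir directory holding a bundle in the [generateBundle()]
#'   layout (genome_a.fa, te_a.tsv, genes_a.gff, motifs.chen,
#'   atac_stage*.bed, chip_*.bed, and optionally genome_b.fa, te_b.tsv,
#'   genes_b.gff, orthologs.tsv)
#' @param outDir output directory, created if needed
#' @param config a [runConfig()]
#' @return invisible list with all stage results (`hitsA`, `coverage`,
#'   `enrichment`, `filtered`, `promoterGenes`, `accessible`, `bound`,
#'   `topAccessible`, `topBound`, `fisher`, `orthology`, `manifest`)
#' @export
runPipeline <- function(inputDir, outDir, config = runConfig()) {
  stopifnot(inherits(config, "RunConfig"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  fp <- function(x) file.path(outDir, x)
  ip <- function(x) file.path(inputDir, x)
  need <- c("genome_a.fa", "te_a.tsv", "genes_a.gff", "motifs.chen")
  miss <- need[!file.exists(ip(need))]
  if (length(miss)) .stopf("missing input file(s): %s (produce with the synth stage)",
                           paste(miss, collapse = ", "))

  ## ---- stage 1: scan species A ----
  genomeA <- readFastaGenome(ip("genome_a.fa"))
  seqlenA <- genomeSeqlengths(genomeA)
  pwms <- readCisbpChen(ip("motifs.chen"))
  tesA <- readTeTable(ip("te_a.tsv"), seqlen = seqlenA)
  gmA <- readGffLite(ip("genes_a.gff"), seqlen = seqlenA)
  .checkChromNames(seqlenA, tesA, "te_a.tsv")
  .checkChromNames(seqlenA, geneSpans(gmA), "genes_a.gff")
  bgA <- backgroundFromFasta(genomeA)
  smsA <- lapply(pwms, logOddsMatrix, bg = bgA)
  hitsA <- scanGenome(genomeA, smsA, pThreshold = config$pThreshold)
  writeHitsBed(hitsA, fp("hits_a.bed"))
  teHitsA <- containedHits(hitsA, tesA)
  writeBed(teHitsA, fp("te_hits_a.bed"),
           extraCols = c("pvalue", "tf_name", "te_type", "te_family"))

  ## ---- stage 2: coverage table ----
  part <- featurePartition(seqlenA, gmA, tesA, upstreamBp = config$upstreamBp)
  coverage <- coverageTable(part)
  .writeTsv(.roundDf(coverage), fp("coverage_table.tsv"),
            comment = "stage: coverage")

  ## ---- stage 3: enrichment + filters + gene lists ----
  enr <- motifTeEnrichment(hitsA, tesA, seqlenA)
  .writeTsv(.roundDf(enr), fp("enrichment_records.tsv"),
            comment = "stage: enrich")
  filt <- filterEnriched(enr, minTeBp = config$minTeBp,
                         minFold = config$minFold, maxP = config$maxP)
  .writeTsv(.roundDf(filt), fp("enrichment_filtered.tsv"),
            comment = "stage: enrich (gate cascade)")
  ## fold matrix, motifs x TE types, for external heatmap tools
  if (nrow(enr)) {
    mat <- tapply(enr$fold, list(enr$name, enr$te_type), identity)
    .writeTsv(data.frame(name = rownames(mat),
                         round(as.data.frame(mat), 3),
                         check.names = FALSE),
              fp("enrichment_matrix.tsv"), comment = "stage: enrich")
  }
  promInc <- promoterRegions(gmA, upstreamBp = config$upstreamBp,
                             exclusive = FALSE)
  enrichedHits <- teHitsA[paste(teHitsA$name, teHitsA$te_type) %in%
                            paste(filt$name, filt$te_type)]
  promoterGenes <- genesWithTeMotifs(promInc, enrichedHits)
  .writeTsv(promoterGenes$pairs, fp("promoter_gene_pairs.tsv"),
            comment = "stage: enrich (TE-enriched motifs in promoters)")

  ## ---- stage 4: chromatin association ----
  atacFiles <- sort(list.files(inputDir, pattern = "^atac_.*\\.bed$",
                               full.names = TRUE))
  chipFiles <- sort(list.files(inputDir, pattern = "^chip_.*\\.bed$",
                               full.names = TRUE))
  accessible <- bound <- topAcc <- topBound <- fisher <- NULL
  atacSet <- NULL
  chipSets <- list()
  if (length(atacFiles)) {
    stages <- lapply(atacFiles, readSummitsBed, seqlen = seqlenA)
    atacSet <- buildSummitRegions(stages, label = "atac", seqlen = seqlenA)
    accessible <- accessibleMotifFractions(hitsA, atacSet, tesA,
                                           minSites = config$accessMinSites,
                                           minPct = config$accessMinPct)
    .writeTsv(.roundDf(accessible), fp("accessible_fractions.tsv"),
              comment = "stage: chromatin")
    accHits <- containedHits(
      hitsA[overlapsAny(hitsA, mergedRegions(atacSet), type = "within",
                        ignore.strand = TRUE)], tesA)
    topAcc <- topTeContributors(accHits)
    .writeTsv(topAcc, fp("top_te_accessible.tsv"), comment = "stage: chromatin")
  }
  if (length(chipFiles)) {
    ids <- sub("^chip_(.*)\\.bed$", "\\1", basename(chipFiles))
    chipSets <- lapply(seq_along(chipFiles), function(i)
      buildSummitRegions(readSummitsBed(chipFiles[i], seqlen = seqlenA),
                         label = ids[i], seqlen = seqlenA))
    names(chipSets) <- ids
    chipSets <- chipSets[names(chipSets) %in% names(pwms)]
    bound <- boundMotifFractions(hitsA, chipSets, tesA,
                                 minRegions = config$boundMinRegions,
                                 minPct = config$boundMinPct)
    .writeTsv(.roundDf(bound), fp("bound_fractions.tsv"),
              comment = "stage: chromatin")
    boundHitList <- lapply(names(chipSets), function(m) {
      mine <- teHitsA[teHitsA$name == m]
      mine[overlapsAny(mine, mergedRegions(chipSets[[m]]), type = "within",
                       ignore.strand = TRUE)]
    })
    boundHits <- do.call(c, boundHitList)
    topBound <- topTeContributors(boundHits)
    .writeTsv(topBound, fp("top_te_bound.tsv"), comment = "stage: chromatin")
    if (!is.null(atacSet)) {
      fisher <- do.call(rbind, lapply(names(chipSets), function(m) {
        res <- accessibilityFisher(chipSets[[m]], atacSet,
                                   teHitsA[teHitsA$name == m])
        data.frame(name = m, te_open = res$table[1, 1],
                   te_closed = res$table[1, 2],
                   other_open = res$table[2, 1],
                   other_closed = res$table[2, 2], p = res$p,
                   degenerate = res$degenerate)
      }))
      .writeTsv(.roundDf(fisher), fp("accessibility_fisher.tsv"),
                comment = paste("stage: chromatin; unit = bound regions;",
                                "rows = contains TE-provided cognate motif;",
                                "columns = overlaps merged ATAC region"))
    }
  }

  ## ---- stage 5: cross-species orthology ----
  orthology <- NULL
  if (file.exists(ip("genome_b.fa"))) {
    genomeB <- readFastaGenome(ip("genome_b.fa"))
    seqlenB <- genomeSeqlengths(genomeB)
    tesB <- readTeTable(ip("te_b.tsv"), seqlen = seqlenB)
    gmB <- readGffLite(ip("genes_b.gff"), seqlen = seqlenB)
    .checkChromNames(seqlenB, tesB, "te_b.tsv")
    map <- readOrthologMap(ip("orthologs.tsv"))
    bgB <- backgroundFromFasta(genomeB)
    smsB <- lapply(pwms, logOddsMatrix, bg = bgB)
    hitsB <- scanGenome(genomeB, smsB, pThreshold = config$pThreshold)
    writeHitsBed(hitsB, fp("hits_b.bed"))
    genesA <- promoterTeMotifGenes(hitsA, tesA, gmA,
                                   upstreamBp = config$upstreamBp)
    genesB <- promoterTeMotifGenes(hitsB, tesB, gmB,
                                   upstreamBp = config$upstreamBp)
    motifsBoth <- sort(union(names(genesA$perMotif), names(genesB$perMotif)))
    orthoRows <- lapply(motifsBoth, function(m) {
      res <- sharedOrthologTest(genesA$perMotif[[m]] %||% character(0),
                                genesB$perMotif[[m]] %||% character(0), map)
      famA <- split(genesA$pairs$te_family[genesA$pairs$name == m],
                    genesA$pairs$gene_id[genesA$pairs$name == m])
      famB <- split(genesB$pairs$te_family[genesB$pairs$name == m],
                    genesB$pairs$gene_id[genesB$pairs$name == m])
      sim <- familySimilarity(res$sharedPairs, famA, famB)
      bs <- boundShared(res$sharedPairs,
                        genesA$pairs[genesA$pairs$name == m, ],
                        chipSets[[m]])
      data.frame(name = m, N = res$N, K = res$K, n = res$n, k = res$k,
                 p = res$p, stars = res$stars,
                 family_similar = sum(sim$similar),
                 family_different = sum(!sim$similar),
                 bound_shared = bs$count)
    })
    orthology <- do.call(rbind, orthoRows)
    .writeTsv(.roundDf(orthology), fp("ortholog_sharing.tsv"),
              comment = "stage: orthology")
  }

  ## ---- manifest ----
  manifest <- data.frame(
    key = c("package_version", "input_dir", "promoter_bp", "scan_p",
            "gate_te_bp", "gate_fold", "gate_p", "gate_access_sites",
            "gate_access_pct", "gate_bound_regions", "gate_bound_pct",
            "seed", "n_motifs", "n_hits_a", "n_te_hits_a",
            "n_enriched_records", "n_pass_cascade",
            "n_promoter_genes_union"),
    value = c(as.character(utils::packageVersion("TEmotifs")),
              basename(inputDir),
              .fmtNum(c(config$upstreamBp, config$pThreshold,
                        config$minTeBp, config$minFold, config$maxP,
                        config$accessMinSites, config$accessMinPct,
                        config$boundMinRegions, config$boundMinPct,
                        config$seed)),
              .fmtNum(c(length(pwms), length(hitsA), length(teHitsA),
                        nrow(enr), nrow(filt),
                        length(promoterGenes$unionGenes)))))
  .writeTsv(manifest, fp("manifest.tsv"), comment = "run manifest")

  invisible(list(hitsA = hitsA, teHitsA = teHitsA, coverage = coverage,
                 enrichment = enr, filtered = filt,
                 promoterGenes = promoterGenes, accessible = accessible,
                 bound = bound, topAccessible = topAcc, topBound = topBound,
                 fisher = fisher, orthology = orthology,
                 manifest = manifest, config = config))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## round numeric columns for report tables (folds/percentages to 4 s.f.;
## p-values kept at full precision)
.roundDf <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !nm %in% c("p", "pvalue"))
      df[[nm]] <- signif(df[[nm]], 6)
  }
  df
}
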