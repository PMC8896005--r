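#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
#'   letterFrequency reverseComplement
NULL

#' Read a genome FASTA
#'
#' Multi-line records are supported; sequence names are truncated at the
#' first whitespace; soft-masked (lowercase) bases are uppercased.
#'
#' @param path FASTA file
#' @return a DNAStringSet
#' @export
readFastaGenome <- function(path) {
  seqs <- readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  DNAStringSet(toupper(seqs))
}

#' Chromosome lengths of a genome
#' @param genome DNAStringSet
#' @return named integer vector
#' @export
genomeSeqlengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

.checkBedCoords <- function(start0, end0, path) {
  bad <- which(!is.finite(start0) | !is.finite(end0) | start0 < 0 |
                 start0 >= end0)
  if (length(bad))
    .stopf("malformed interval in %s at data line %d: start=%s end=%s",
           path, bad[1], start0[bad[1]], end0[bad[1]])
}

#' Read a BED file into a GRanges
#'
#' BED coordinates (0-based half-open) are converted to the 1-based closed
#' GRanges convention. Up to 6 columns are used (chrom, start, end, name,
#' score, strand); lines starting with `#`, `track` or `browser` are
#' skipped.
#'
#' @param path BED file
#' @param seqlen optional named chromosome lengths attached to the result
#' @return GRanges with `name` and `score` metadata when present
#' @export
readBed <- function(path, seqlen = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(GRanges(seqlengths = seqlen))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- min(lengths(f))
  get <- function(i) vapply(f, `[[`, character(1), i)
  start0 <- as.numeric(get(2)); end0 <- as.numeric(get(3))
  .checkBedCoords(start0, end0, path)
  std <- if (ncol >= 6) sub("^\\.$", "*", get(6)) else "*"
  gr <- GRanges(get(1), IRanges(start0 + 1, end0), strand = std)
  if (ncol >= 4) gr$name <- get(4)
  if (ncol >= 5) gr$score <- suppressWarnings(as.numeric(get(5)))
  if (!is.null(seqlen)) {
    seqlevels(gr) <- union(names(seqlen), seqlevels(gr))
    seqlengths(gr)[names(seqlen)] <- seqlen
  }
  sort(gr, ignore.strand = TRUE)
}

#' Write a GRanges as BED
#'
#' Output is 0-based half-open, sorted by chromosome and start, with
#' deterministic formatting. Metadata columns beyond name/score/strand can
#' be appended as extra tab-separated columns.
#'
#' @param gr GRanges; `name` and `score` metadata are used when present
#' @param path output file
#' @param extraCols character vector of metadata column names to append
#' @return the path, invisibly
#' @export
writeBed <- function(gr, path, extraCols = character(0)) {
  gr <- sort(gr, ignore.strand = TRUE)
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    start = format(start(gr) - 1L, scientific = FALSE, trim = TRUE),
    end = format(end(gr), scientific = FALSE, trim = TRUE),
    name = if (!is.null(gr$name)) gr$name else ".",
    score = if (!is.null(gr$score)) .fmtNum(gr$score) else "0",
    strand = sub("^\\*$", ".", as.character(strand(gr))),
    stringsAsFactors = FALSE)
  for (ec in extraCols) df[[ec]] <- .fmtNum2(mcols(gr)[[ec]])
  con <- file(path, "wt")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

.fmtNum2 <- function(x) {
  if (is.numeric(x)) .fmtNum(x) else as.character(x)
}

#' Read a RepeatMasker-flavoured TE annotation table
#'
#' Tab-separated columns: chrom, start, end, te_type, te_family,
#' repeat_class; BED-style 0-based half-open coordinates; `#` comment lines
#' skipped.
#'
#' @param path TE table file
#' @param seqlen optional named chromosome lengths
#' @return GRanges with `te_type`, `te_family`, `repeat_class`
#' @export
readTeTable <- function(path, seqlen = NULL) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   col.names = c("chrom", "start", "end", "te_type",
                                 "te_family", "repeat_class"),
                   colClasses = c("character", "numeric", "numeric",
                                  "character", "character", "character"))
  if (nrow(df) == 0L) return(GRanges(seqlengths = seqlen))
  .checkBedCoords(df$start, df$end, path)
  gr <- GRanges(df$chrom, IRanges(df$start + 1, df$end))
  gr$te_type <- df$te_type
  gr$te_family <- df$te_family
  gr$repeat_class <- df$repeat_class
  if (!is.null(seqlen)) {
    seqlevels(gr) <- union(names(seqlen), seqlevels(gr))
    seqlengths(gr)[names(seqlen)] <- seqlen
  }
  sort(gr, ignore.strand = TRUE)
}

#' Write a TE annotation table
#' @param tes GRanges with `te_type`, `te_family`, `repeat_class`
#' @param path output file
#' @return the path, invisibly
#' @export
writeTeTable <- function(tes, path) {
  tes <- sort(tes, ignore.strand = TRUE)
  df <- data.frame(chrom = as.character(seqnames(tes)),
                   start = start(tes) - 1L, end = end(tes),
                   te_type = tes$te_type, te_family = tes$te_family,
                   repeat_class = tes$repeat_class)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tte_type\tte_family\trepeat_class", con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read gene models from a GFF-lite file
#'
#' Nine tab-separated columns in the GFF tradition: seqid, source, type,
#' start, end, score, strand, frame, attributes. Coordinates are 1-based
#' inclusive and converted on ingest. Recognized feature types: `gene`,
#' `operon`, `coding_exon` (or `CDS`), `five_prime_UTR`, `three_prime_UTR`,
#' `intron`. Attributes use `key=value;` pairs with keys `gene_id` and
#' `operon_id`. Introns are derived from gene minus exons/UTRs when the
#' file has none.
#'
#' @param path GFF-lite file
#' @param seqlen optional named chromosome lengths
#' @return a [GeneModels-class] object
#' @export
readGffLite <- function(path, seqlen = NULL) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   quote = "", stringsAsFactors = FALSE,
                   col.names = c("seqid", "source", "type", "start", "end",
                                 "score", "strand", "frame", "attr"))
  attrVal <- function(attr, key) {
    m <- regmatches(attr, regexec(paste0("(^|;)", key, "=([^;]+)"), attr))
    vapply(m, function(x) if (length(x) >= 3) x[3] else NA_character_,
           character(1))
  }
  mk <- function(rows, idKey = "gene_id") {
    if (nrow(rows) == 0L) {
      g <- GRanges(seqlengths = seqlen)
      mcols(g)[[idKey]] <- character(0)
      return(g)
    }
    bad <- which(rows$start < 1 | rows$end < rows$start)
    if (length(bad)) .stopf("malformed interval in %s (1-based line %d)",
                            path, bad[1])
    g <- GRanges(rows$seqid, IRanges(rows$start, rows$end),
                 strand = rows$strand)
    if (!is.null(seqlen)) {
      seqlevels(g) <- union(names(seqlen), seqlevels(g))
      seqlengths(g)[names(seqlen)] <- seqlen
    }
    mcols(g)[[idKey]] <- attrVal(rows$attr, idKey)
    g
  }
  genes <- mk(df[df$type == "gene", ])
  genes$operon_id <- attrVal(df$attr[df$type == "gene"], "operon_id")
  operons <- mk(df[df$type == "operon", ], "operon_id")
  exons <- mk(df[df$type %in% c("coding_exon", "CDS"), ])
  utr5 <- mk(df[df$type == "five_prime_UTR", ])
  utr3 <- mk(df[df$type == "three_prime_UTR", ])
  intr <- df[df$type == "intron", ]
  GeneModels(genes = genes, exons = exons, utr5 = utr5, utr3 = utr3,
             introns = if (nrow(intr)) mk(intr) else NULL,
             operons = operons)
}

#' Write gene models to a GFF-lite file
#' @param gm a [GeneModels-class] object
#' @param path output file
#' @return the path, invisibly
#' @export
writeGffLite <- function(gm, path) {
  rows <- function(gr, type, idKey) {
    if (length(gr) == 0L) return(NULL)
    attr <- paste0(idKey, "=", mcols(gr)[[idKey]])
    if (identical(idKey, "gene_id") && !is.null(gr$operon_id)) {
      has <- !is.na(gr$operon_id)
      attr[has] <- paste0(attr[has], ";operon_id=", gr$operon_id[has])
    }
    data.frame(seqid = as.character(seqnames(gr)), source = "TEmotifs",
               type = type, start = start(gr), end = end(gr), score = ".",
               strand = as.character(strand(gr)), frame = ".", attr = attr)
  }
  df <- rbind(rows(geneSpans(gm), "gene", "gene_id"),
              rows(operonSpans(gm), "operon", "operon_id"),
              rows(codingExons(gm), "coding_exon", "gene_id"),
              rows(fivePrimeUTRs(gm), "five_prime_UTR", "gene_id"),
              rows(threePrimeUTRs(gm), "three_prime_UTR", "gene_id"),
              rows(geneIntrons(gm), "intron", "gene_id"))
  df <- df[order(df$seqid, df$start, df$type, df$attr), ]
  con <- file(path, "wt")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a one-to-one ortholog map
#'
#' Two tab-separated columns: gene id in species A, gene id in species B.
#' The map must be strictly one-to-one.
#'
#' @param path TSV file
#' @return data.frame with columns `idA`, `idB`
#' @export
readOrthologMap <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE, col.names = c("idA", "idB"))
  if (anyDuplicated(df$idA) || anyDuplicated(df$idB))
    .stopf("ortholog map in %s is not one-to-one", path)
  df
}

#' Read peak summits from a BED file
#'
#' Summits must be single-base records (end = start + 1 in BED
#' coordinates); MACS2-style name suffixes are tolerated.
#'
#' @param path BED file of summits
#' @param seqlen optional named chromosome lengths
#' @return GRanges of width-1 positions
#' @export
readSummitsBed <- function(path, seqlen = NULL) {
  gr <- readBed(path, seqlen = seqlen)
  if (length(gr) && any(width(gr) != 1L))
    .stopf("summits in %s must be single-base intervals", path)
  gr
}
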