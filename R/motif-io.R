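#' Read motifs in the Cis-BP "chen" tab dialect
#'
#' Each motif block starts with a `>` header carrying the motif id and
#' (optionally) the TF name, followed by an optional `Pos A C G T` column
#' header and one tab-separated row per position: position index then four
#' probability columns. Rows whose sum deviates from 1 by less than 1e-3
#' are renormalized; larger deviations or non-numeric cells are rejected
#' with the offending line number.
#'
#' @param path motif file
#' @return list of [PWMotif-class] objects, named by motif id
#' @export
readCisbpChen <- function(path) {
  lines <- readLines(path)
  out <- list()
  cur <- NULL; curId <- NULL; curTf <- NULL
  flush <- function() {
    if (is.null(curId)) return()
    if (length(cur) == 0L) .stopf("motif block %s has no rows", curId)
    m <- do.call(rbind, cur)
    out[[curId]] <<- PWMotif(curId, m, tfName = curTf)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      flush()
      parts <- strsplit(sub("^>\\s*", "", ln), "[\t ]+")[[1]]
      curId <- parts[1]
      curTf <- if (length(parts) >= 2) parts[2] else parts[1]
      cur <- list()
      next
    }
    fields <- strsplit(ln, "[\t ]+")[[1]]
    if (identical(toupper(fields[1]), "POS")) next
    if (is.null(curId)) .stopf("%s line %d: row outside a motif block", path, i)
    if (length(fields) < 5)
      .stopf("%s line %d: expected position + 4 probability columns", path, i)
    vals <- suppressWarnings(as.numeric(fields[2:5]))
    if (anyNA(vals)) .stopf("%s line %d: non-numeric probability cell", path, i)
    s <- sum(vals)
    if (abs(s - 1) >= 1e-3)
      .stopf("%s line %d: row sum %.6f deviates from 1 by >= 1e-3", path, i, s)
    if (abs(s - 1) > 1e-12) vals <- vals / s
    cur[[length(cur) + 1L]] <- vals
  }
  flush()
  out
}

#' Write motifs in the Cis-BP "chen" tab dialect
#' @param pwms list of [PWMotif-class] objects
#' @param path output file
#' @return the path, invisibly
#' @export
writeCisbpChen <- function(pwms, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s\t%s", motifId(p), tfName(p)), con)
    writeLines("Pos\tA\tC\tG\tT", con)
    m <- probMatrix(p)
    for (j in seq_len(ncol(m)))
      writeLines(paste(c(j, formatC(m[, j], format = "g", digits = 17)),
                       collapse = "\t"), con)
  }
  invisible(path)
}

#' Read motifs in MEME minimal format
#'
#' Parses the `MOTIF` blocks of a MEME-minimal file (alphabet, background
#' and letter-probability matrix lines); only the ACGT alphabet is
#' supported.
#'
#' @param path MEME file
#' @return list with elements `motifs` (named list of [PWMotif-class]) and
#'   `background` (a [ZeroOrderBackground-class], uniform when absent)
#' @export
readMemeMotifs <- function(path) {
  lines <- readLines(path)
  motifs <- list()
  bg <- ZeroOrderBackground()
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "Background letter frequencies")) {
      f <- strsplit(trimws(lines[i + 1L]), "[ \t]+")[[1]]
      v <- as.numeric(f[seq(2, 8, by = 2)])
      names(v) <- f[seq(1, 7, by = 2)]
      bg <- ZeroOrderBackground(v[DNA_BASES])
      i <- i + 2L
      next
    }
    if (startsWith(ln, "MOTIF")) {
      parts <- strsplit(ln, "[ \t]+")[[1]]
      id <- parts[2]
      tf <- if (length(parts) >= 3) parts[3] else id
      ## seek letter-probability header
      j <- i + 1L
      while (j <= length(lines) &&
             !startsWith(trimws(lines[j]), "letter-probability matrix"))
        j <- j + 1L
      if (j > length(lines)) .stopf("MOTIF %s has no probability matrix", id)
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
      rows <- lapply(seq_len(w), function(k)
        as.numeric(strsplit(trimws(lines[j + k]), "[ \t]+")[[1]]))
      motifs[[id]] <- PWMotif(id, do.call(rbind, rows), tfName = tf)
      i <- j + w + 1L
      next
    }
    i <- i + 1L
  }
  list(motifs = motifs, background = bg)
}

#' Write motifs in MEME minimal format
#' @param pwms list of [PWMotif-class] objects
#' @param path output file
#' @param background optional [ZeroOrderBackground-class] written into the
#'   header
#' @return the path, invisibly
#' @export
writeMemeMotifs <- function(pwms, path, background = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", ""), con)
  if (!is.null(background)) {
    writeLines("Background letter frequencies", con)
    writeLines(paste(sprintf("%s %.6f", DNA_BASES, bgFreq(background)),
                     collapse = " "), con)
    writeLines("", con)
  }
  for (p in pwms) {
    m <- probMatrix(p)
    writeLines(sprintf("MOTIF %s %s", motifId(p), tfName(p)), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", ncol(m)),
      con)
    for (j in seq_len(ncol(m)))
      writeLines(paste(formatC(m[, j], format = "f", digits = 6),
                       collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}
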