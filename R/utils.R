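#' @importFrom methods new validObject is slot
#' @importFrom stats pbinom phyper fisher.test runif rbinom setNames
#' @importFrom utils read.table write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

## base -> integer code lookup over raw byte values; N and anything else -> NA
.baseCodes <- local({
  codes <- rep(NA_integer_, 256L)
  codes[utf8ToInt("A")] <- 1L; codes[utf8ToInt("a")] <- 1L
  codes[utf8ToInt("C")] <- 2L; codes[utf8ToInt("c")] <- 2L
  codes[utf8ToInt("G")] <- 3L; codes[utf8ToInt("g")] <- 3L
  codes[utf8ToInt("T")] <- 4L; codes[utf8ToInt("t")] <- 4L
  codes
})

#' Encode a DNA sequence as integer base codes
#'
#' A=1, C=2, G=3, T=4; any other letter (N, IUPAC ambiguity) becomes NA.
#' @param x character scalar or object coercible via `as.character`
#' @return integer vector of length `nchar(x)`
#' @keywords internal
encodeDNA <- function(x) {
  .baseCodes[utf8ToInt(as.character(x))]
}

## complement of integer codes: 1<->4, 2<->3
.complementCodes <- function(v) 5L - v

#' Derive a reproducible sub-seed for a named random stream
#'
#' One global integer seed drives independent named substreams so that
#' changing one part of a simulation plan does not perturb the draws of
#' another. The stream name is hashed order-sensitively and mixed with the
#' seed modulo 2^31 - 1.
#' @param seed integer master seed
#' @param stream character stream name
#' @return integer sub-seed in [0, 2^31 - 1)
#' @export
subSeed <- function(seed, stream) {
  iv <- utf8ToInt(stream)
  h <- sum(iv * seq_along(iv) * 131) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

#' Evaluate an expression under a named random substream
#'
#' Sets the RNG deterministically from [subSeed()] and restores the caller's
#' RNG state afterwards.
#' @param seed integer master seed
#' @param stream character stream name
#' @param expr expression to evaluate
#' @return value of `expr`
#' @export
withSubSeed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(subSeed(seed, stream), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

## fixed-format numbers for deterministic file output
.fmtNum <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", trimws(formatC(x, format = "g", digits = digits)))
}

.writeTsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.msgf <- function(fmt, ...) message(sprintf(fmt, ...))
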