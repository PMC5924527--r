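#' @useDynLib genomeprep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.datatable.aware <- TRUE

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over plain character DNA. IUPAC bases other
#' than A/C/G/T/N are not supported.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, case-insensitive;
#'   returned uppercase).
#' @return character vector of the same length.
#' @examples
#' revcomp(c("ACGT", "GATTACA"))
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  up <- toupper(x)
  bad <- grepl("[^ACGTN]", up)
  if (any(bad)) {
    stop("non-ACGTN base in sequence ", which(bad)[1])
  }
  comp <- chartr("ACGTN", "TGCAN", up)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Reverse a string (used for quality strings alongside revcomp).
str_rev <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Round half away from zero
#'
#' Decimal rounding where ties go away from zero (the convention of most
#' assembly-report tables), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Decode a Phred-33 quality string to integer scores.
phred_decode <- function(qual) {
  if (nchar(qual) == 0L) return(integer(0))
  utf8ToInt(qual) - 33L
}

# Encode integer Phred scores as a Phred-33 string.
phred_encode <- function(scores) {
  if (length(scores) == 0L) return("")
  intToUtf8(as.integer(scores) + 33L)
}
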