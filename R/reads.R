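#' Sequence read containers
#'
#' A `read_set` is the package's carrier for FASTQ records: a data.frame with
#' columns `id` (record identifier, no leading `@`), `seq` (uppercase DNA over
#' A/C/G/T/N) and `qual` (Phred-33 encoded quality string of the same length).
#' Keeping qualities encoded keeps large read sets compact; decode per read
#' with [phred()].
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of DNA sequences.
#' @param qual character vector of Phred-33 quality strings, or a list of
#'   integer Phred scores (encoded on construction).
#' @return a `read_set` (classed data.frame).
#' @export
read_set <- function(id, seq, qual) {
  if (is.list(qual)) qual <- vapply(qual, phred_encode, character(1))
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  seq <- toupper(seq)
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop("sequence/quality length mismatch for read ", bad[1],
         " ('", id[bad[1]], "')")
  }
  structure(
    data.frame(id = as.character(id), seq = seq, qual = as.character(qual),
               stringsAsFactors = FALSE),
    class = c("read_set", "data.frame")
  )
}

#' @describeIn read_set decoded Phred scores of read `i` (integer vector).
#' @param reads a `read_set`.
#' @param i record index.
#' @export
phred <- function(reads, i = 1L) phred_decode(reads$qual[[i]])

#' @export
print.read_set <- function(x, ...) {
  cat("read_set with", nrow(x), "reads\n")
  if (nrow(x)) {
    n <- min(nrow(x), 6L)
    len <- nchar(x$seq[seq_len(n)])
    cat(paste0("  ", x$id[seq_len(n)], " (", len, " bp)"), sep = "\n")
    if (nrow(x) > n) cat("  ...\n")
  }
  invisible(x)
}

#' Read a FASTQ file
#'
#' Parses 4-line FASTQ records (Phred-33). Sequences are uppercased; `N`
#' bases are allowed. Malformed records (missing `+` separator, sequence and
#' quality of different lengths, truncated final record) raise an error that
#' names the offending record index.
#'
#' @param path path to an uncompressed or gzipped FASTQ file.
#' @return a [read_set()].
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  # trailing blank lines are tolerated
  while (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0L) return(read_set(character(0), character(0), character(0)))
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ record ", length(lines) %/% 4L + 1L, " in ", path)
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(substr(hdr, 1L, 1L) != "@" | substr(plus, 1L, 1L) != "+")
  if (length(bad)) stop("malformed FASTQ record ", bad[1], " in ", path)
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop("sequence/quality length mismatch at FASTQ record ", bad[1],
         " in ", path)
  }
  id <- sub("\\s.*$", "", substring(hdr, 2L))
  read_set(id, seq, qual)
}

#' Write a FASTQ file
#'
#' @param reads a [read_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- character(4L * nrow(reads))
  out[seq(1L, by = 4L, length.out = nrow(reads))] <- paste0("@", reads$id)
  out[seq(2L, by = 4L, length.out = nrow(reads))] <- reads$seq
  out[seq(3L, by = 4L, length.out = nrow(reads))] <- "+"
  out[seq(4L, by = 4L, length.out = nrow(reads))] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a named
#' uppercase character vector, the representation the rest of the package
#' works with.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Paired reads
#'
#' Two parallel [read_set()]s of equal cardinality plus a library identifier.
#'
#' @param read1,read2 `read_set`s of equal length.
#' @param library_id library label carried through clipping reports.
#' @return a `read_pair_set`.
#' @export
read_pair_set <- function(read1, read2, library_id = "lib") {
  stopifnot(inherits(read1, "read_set"), inherits(read2, "read_set"),
            nrow(read1) == nrow(read2))
  if (nrow(read1) == 0L) stop("empty read pair set")
  structure(list(read1 = read1, read2 = read2, library_id = library_id),
            class = "read_pair_set")
}

#' @export
print.read_pair_set <- function(x, ...) {
  cat("read_pair_set:", nrow(x$read1), "pairs, library", x$library_id, "\n")
  invisible(x)
}
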