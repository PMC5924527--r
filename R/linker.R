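#' Linker search configuration
#'
#' Parameters of the ungapped linker scan used for Cre-Lox / Nextera
#' mate-pair junction detection. The distinguishing rule is the *continuous
#' core*: a candidate alignment only qualifies if it contains an exact match
#' run of at least `min_core` bp. Long junction linkers produce many spurious
#' partial hits under a plain matching-bases criterion; the core requirement
#' restores specificity without sacrificing sensitivity to read-through
#' junctions.
#'
#' @param linker_sequence DNA string of the junction linker.
#' @param min_core minimum length (bp) of a continuous exact-match run
#'   within the aligned span (default 9).
#' @param min_identity minimum fraction of matching bases over the aligned
#'   span (default 0.8).
#' @param search_both_strands also scan the reverse complement of the
#'   linker (default TRUE).
#' @return a `linker_config` list.
#' @export
linker_config <- function(linker_sequence, min_core = 9L, min_identity = 0.8,
                          search_both_strands = TRUE) {
  linker_sequence <- toupper(linker_sequence)
  stopifnot(nchar(linker_sequence) >= 1L,
            min_core >= 1L, min_core <= nchar(linker_sequence),
            min_identity > 0, min_identity <= 1)
  structure(list(linker_sequence = linker_sequence,
                 linker_rc = revcomp(linker_sequence),
                 min_core = as.integer(min_core),
                 min_identity = min_identity,
                 search_both_strands = isTRUE(search_both_strands)),
            class = "linker_config")
}

#' Find the best qualifying linker match in a read
#'
#' Scans every ungapped offset of the linker (and, by default, its reverse
#' complement) against the read, including partial overhangs at the read
#' ends whose aligned span is at least `min_core`. A candidate qualifies
#' when both `matches / aligned_length >= min_identity` and its longest
#' continuous exact-match run is at least `min_core` bp. Among qualifying
#' candidates the one with the most matching bases wins; ties break to the
#' leftmost read offset, then to the `+` strand.
#'
#' @param sequence a DNA string (one read).
#' @param config a [linker_config()].
#' @return a list with `read_start`, `read_end` (0-based half-open span of
#'   the linker on the read), `matches`, `aligned_length`,
#'   `longest_exact_run`, `strand`; or `NULL` when no candidate qualifies.
#' @export
find_linker <- function(sequence, config) {
  stopifnot(inherits(config, "linker_config"), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty sequence")
  hits <- find_linker_many(sequence, config)
  if (!hits$found[1]) return(NULL)
  list(read_start = hits$read_start[1], read_end = hits$read_end[1],
       matches = hits$matches[1], aligned_length = hits$aligned_length[1],
       longest_exact_run = hits$longest_exact_run[1],
       strand = hits$strand[1])
}

# Vectorised scan over many reads; returns parallel vectors incl. `found`.
# read_start/read_end are 0-based half-open.
find_linker_many <- function(sequences, config) {
  linker_scan_cpp(toupper(sequences), config$linker_sequence,
                  config$linker_rc, config$min_core, config$min_identity,
                  config$search_both_strands)
}

#' Clip mate-pair reads at junction linkers
#'
#' Applies the linker scan to both members of every pair and truncates each
#' linker-containing read to the bases before the linker start
#' (`[0, read_start)`). Pairs are categorised by which members contained a
#' linker: `BOTH`, `READ1_ONLY`, `READ2_ONLY`, or `NEITHER`. A member whose
#' kept prefix is shorter than `min_keep` bp is flagged too-short; such
#' pairs should be demoted to single-end output (the surviving mate keeps
#' paired files at equal cardinality).
#'
#' @param pairs a [read_pair_set()].
#' @param config a [linker_config()].
#' @param min_keep minimum kept length (bp) after truncation (default 25).
#' @return a `clip_result`: list with the clipped `pairs`, per-pair
#'   `category` factor, logical `too_short1`/`too_short2`, and a `counts`
#'   table over categories.
#' @export
clip_pair <- function(pairs, config, min_keep = 25L) {
  stopifnot(inherits(pairs, "read_pair_set"))
  h1 <- find_linker_many(pairs$read1$seq, config)
  h2 <- find_linker_many(pairs$read2$seq, config)
  r1 <- truncate_at(pairs$read1, h1)
  r2 <- truncate_at(pairs$read2, h2)
  category <- ifelse(h1$found & h2$found, "BOTH",
              ifelse(h1$found, "READ1_ONLY",
              ifelse(h2$found, "READ2_ONLY", "NEITHER")))
  category <- factor(category,
                     levels = c("BOTH", "READ1_ONLY", "READ2_ONLY", "NEITHER"))
  out <- list(
    pairs = read_pair_set(r1, r2, pairs$library_id),
    category = category,
    too_short1 = nchar(r1$seq) < min_keep,
    too_short2 = nchar(r2$seq) < min_keep,
    min_keep = as.integer(min_keep),
    counts = table(category)
  )
  class(out) <- "clip_result"
  out
}

# Truncate reads to [0, read_start) where a linker hit was found.
truncate_at <- function(reads, hits) {
  keep <- ifelse(hits$found, hits$read_start, nchar(reads$seq))
  read_set(reads$id, substr(reads$seq, 1L, keep), substr(reads$qual, 1L, keep))
}

#' @export
print.clip_result <- function(x, ...) {
  cat("linker clipping of", length(x$category), "pairs:\n")
  print(x$counts)
  ns <- sum(x$too_short1 | x$too_short2)
  cat(ns, "pairs with a member shorter than", x$min_keep,
      "bp after clipping\n")
  invisible(x)
}

#' Split a 454 mate-pair read at its linker
#'
#' Finds the linker in the read and splits it into the forward segment (the
#' bases before the linker) and the reverse segment (the bases after it).
#' Trailing low-quality bases (Phred < `trim_quality`) are trimmed from the
#' 3' end of the reverse segment *before* it is reverse-complemented to
#' match forward-orientation mate-pair conventions; its quality string is
#' reversed alongside.
#'
#' @param read one-row [read_set()] (or a row index into a larger set via
#'   `reads[i, ]`).
#' @param config a [linker_config()].
#' @param trim_quality Phred threshold for trailing-quality trimming of the
#'   reverse segment (default 20).
#' @return list with `split = TRUE`, `forward` and `reverse_rc` one-row
#'   `read_set`s, and the linker `match`; or `list(split = FALSE)` when the
#'   read has no qualifying linker.
#' @export
split_454 <- function(read, config, trim_quality = 20L) {
  stopifnot(nrow(read) == 1L)
  m <- find_linker(read$seq, config)
  if (is.null(m)) return(list(split = FALSE))
  len <- nchar(read$seq)
  fwd <- read_set(paste0(read$id, "/fwd"),
                  substr(read$seq, 1L, m$read_start),
                  substr(read$qual, 1L, m$read_start))
  rseq <- substring(read$seq, m$read_end + 1L, len)
  rqual <- substring(read$qual, m$read_end + 1L, len)
  # drop trailing bases below the quality threshold, then reverse-complement
  q <- phred_decode(rqual)
  keep <- length(q)
  while (keep > 0L && q[keep] < trim_quality) keep <- keep - 1L
  rseq <- substr(rseq, 1L, keep)
  rqual <- substr(rqual, 1L, keep)
  rev <- read_set(paste0(read$id, "/rev"), revcomp(rseq), str_rev(rqual))
  list(split = TRUE, forward = fwd, reverse_rc = rev, match = m)
}

#' Adapter contamination filter configuration
#'
#' @param adapter_sequences character vector of adapter sequences.
#' @param kmer_length k for the exact k-mer screen (default 11); must not
#'   exceed the shortest adapter.
#' @param min_terminal_match minimum exact terminal prefix/suffix overlap
#'   (bp) for the read-end screen (default 8).
#' @return an `adapter_filter_config` list.
#' @export
adapter_filter_config <- function(adapter_sequences, kmer_length = 11L,
                                  min_terminal_match = 8L) {
  if (length(adapter_sequences) == 0L) stop("empty adapter list")
  adapter_sequences <- toupper(adapter_sequences)
  stopifnot(kmer_length <= min(nchar(adapter_sequences)),
            min_terminal_match >= 1L)
  structure(list(adapter_sequences = adapter_sequences,
                 kmer_length = as.integer(kmer_length),
                 min_terminal_match = as.integer(min_terminal_match)),
            class = "adapter_filter_config")
}

#' Drop whole reads contaminated by adapters
#'
#' Two-stage whole-read filter; reads are never trimmed, only kept or
#' dropped (assemblers that model raw read ends require unmodified input).
#' Stage 1 drops a read if any exact adapter k-mer (both strands) occurs
#' anywhere in it — the long-fragment screen. Stage 2 drops a read if an
#' exact adapter prefix of at least `min_terminal_match` bp ends the read,
#' or an exact adapter suffix of that length starts it (adapter running off
#' either read end) — the short-terminal-fragment screen.
#'
#' @param reads a [read_set()].
#' @param config an [adapter_filter_config()].
#' @return list with `kept` (a `read_set`), `dropped` (count),
#'   `dropped_stage1`, `dropped_stage2`.
#' @export
drop_adapter_reads <- function(reads, config) {
  stopifnot(inherits(config, "adapter_filter_config"))
  seqs <- reads$seq
  drop1 <- logical(nrow(reads))
  k <- config$kmer_length
  adapters <- unique(c(config$adapter_sequences,
                       revcomp(config$adapter_sequences)))
  kmers <- unique(unlist(lapply(adapters, function(a) {
    n <- nchar(a)
    substring(a, 1:(n - k + 1L), k:n)
  })))
  for (km in kmers) {
    drop1 <- drop1 | grepl(km, seqs, fixed = TRUE)
  }
  drop2 <- logical(nrow(reads))
  rl <- nchar(seqs)
  for (a in adapters) {
    n <- nchar(a)
    for (t in seq(config$min_terminal_match, n)) {
      pre <- substr(a, 1L, t)            # adapter start at read 3' end
      suf <- substring(a, n - t + 1L, n) # adapter end at read 5' end
      drop2 <- drop2 |
        (rl >= t & substring(seqs, rl - t + 1L, rl) == pre) |
        (rl >= t & substr(seqs, 1L, t) == suf)
    }
  }
  dropped <- drop1 | drop2
  kept <- reads[!dropped, , drop = FALSE]
  class(kept) <- c("read_set", "data.frame")
  list(kept = kept, dropped = sum(dropped),
       dropped_stage1 = sum(drop1), dropped_stage2 = sum(!drop1 & drop2))
}
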