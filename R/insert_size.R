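#' Parse paired alignments from plain-text SAM
#'
#' Reads a SAM file (text, with `@SQ` header lines supplying contig
#' lengths), joins primary alignments of the two mates by QNAME, and
#' derives pair geometry. Secondary (0x100) and supplementary (0x800)
#' records are ignored; unmapped mates and QNAMEs without exactly two
#' primary records are skipped and counted. Positions are converted to the
#' package's 0-based convention; the mapped reference span is taken from
#' the CIGAR (M/D/N/=/X operations).
#'
#' @param path path to a SAM file.
#' @return a `pair_alignments` data.frame with columns `qname`, `contig_id`
#'   (of read 1; NA-mixed pairs keep both via `contig_id2`), `contig_length`,
#'   `pos1`, `pos2` (0-based leftmost), `read_len1`, `read_len2` (reference
#'   span), `mapq1`, `mapq2`, `orientation` ("FR", "RF", "TANDEM"),
#'   `same_contig`; `attr(,"skipped_unpaired")` counts dropped QNAMEs.
#' @export
parse_sam_pairs <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]

  sq <- hdr[startsWith(hdr, "@SQ")]
  sq_name <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  sq_len <- as.numeric(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  names(sq_len) <- sq_name

  if (length(body) == 0L) {
    out <- empty_pair_alignments()
    attr(out, "skipped_unpaired") <- 0L
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  f <- function(i) vapply(fields, `[`, character(1), i)
  qname <- f(1)
  flag <- as.integer(f(2))
  rname <- f(3)
  pos1b <- as.numeric(f(4))
  mapq <- as.integer(f(5))
  cigar <- f(6)

  keep <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L &
    bitwAnd(flag, 0x4L) == 0L & rname != "*"
  qname <- qname[keep]; flag <- flag[keep]; rname <- rname[keep]
  pos1b <- pos1b[keep]; mapq <- mapq[keep]; cigar <- cigar[keep]

  unknown <- setdiff(unique(rname), sq_name)
  if (length(unknown)) {
    stop("alignment references contig absent from @SQ header: ", unknown[1])
  }

  dt <- data.table::data.table(
    qname = qname, rname = rname, pos = pos1b - 1,
    mapq = mapq, span = cigar_ref_span(cigar),
    rev = bitwAnd(flag, 0x10L) != 0L,
    first = bitwAnd(flag, 0x40L) != 0L
  )
  counts <- dt[, .N, by = "qname"]
  good <- counts$qname[counts$N == 2L]
  skipped <- nrow(counts) - length(good)
  dt <- dt[dt$qname %in% good, ]
  data.table::setorderv(dt, c("qname", "first"), order = c(1L, -1L))
  odd <- seq(1L, nrow(dt), by = 2L)
  even <- odd + 1L
  a <- dt[odd, ]; b <- dt[even, ]

  same <- a$rname == b$rname
  # orientation from the leftmost mate's strand on the same contig
  a_left <- a$pos <= b$pos
  up_rev <- ifelse(a_left, a$rev, b$rev)
  dn_rev <- ifelse(a_left, b$rev, a$rev)
  orientation <- ifelse(a$rev == b$rev, "TANDEM",
                 ifelse(!up_rev & dn_rev, "FR", "RF"))

  out <- data.frame(
    qname = a$qname,
    contig_id = a$rname, contig_id2 = b$rname,
    contig_length = unname(sq_len[a$rname]),
    pos1 = a$pos, pos2 = b$pos,
    read_len1 = a$span, read_len2 = b$span,
    mapq1 = a$mapq, mapq2 = b$mapq,
    orientation = orientation,
    same_contig = same,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pair_alignments", "data.frame")
  attr(out, "skipped_unpaired") <- skipped
  out
}

empty_pair_alignments <- function() {
  out <- data.frame(qname = character(0), contig_id = character(0),
                    contig_id2 = character(0), contig_length = numeric(0),
                    pos1 = numeric(0), pos2 = numeric(0),
                    read_len1 = numeric(0), read_len2 = numeric(0),
                    mapq1 = integer(0), mapq2 = integer(0),
                    orientation = character(0), same_contig = logical(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("pair_alignments", "data.frame")
  out
}

# Reference span consumed by a CIGAR string (M/D/N/=/X).
cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (cg == "*") return(0)
    lens <- as.numeric(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
    sum(lens[ops %in% c("M", "D", "N", "=", "X")])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Estimate the insert-size distribution from pair alignments
#'
#' The insert is the outer distance `max(pos + len) - min(pos)` of the two
#' mates on the contig (the convention scaffolders consume). Only pairs
#' that survive four gates contribute: both mates on the same contig, the
#' contig at least `contig_gate_factor` times the *target* insert size
#' (short contigs bias the estimate towards short artifactual inserts),
#' the expected orientation, and both mapping qualities at least
#' `min_mapq`. A single robust pass then removes outliers beyond
#' `mad_multiplier` median absolute deviations (normal-consistent MAD,
#' [stats::mad()]) from the median before the mean and sd are computed.
#'
#' @param pairs a `pair_alignments` data.frame from [parse_sam_pairs()].
#' @param target_insert nominal library insert size (bp); drives the
#'   contig-length gate.
#' @param expected_orientation "FR" (default) or "RF"; TANDEM pairs are
#'   always rejected.
#' @param min_mapq minimum mapping quality for both mates (default 20).
#' @param contig_gate_factor contig length must be at least this multiple
#'   of `target_insert` (default 3).
#' @param mad_multiplier outlier half-width in MADs (default 10).
#' @return an `insert_size_estimate`: list with `mean`, `sd`, `median`,
#'   `n_used`, `n_rejected_by_contig_gate`, `n_rejected_other`,
#'   `n_outliers_removed`, and the gated `inserts`.
#' @export
estimate_insert <- function(pairs, target_insert,
                            expected_orientation = c("FR", "RF"),
                            min_mapq = 20L, contig_gate_factor = 3,
                            mad_multiplier = 10) {
  expected_orientation <- match.arg(expected_orientation)
  stopifnot(target_insert > 0)
  same <- pairs$same_contig
  gate_contig <- same & pairs$contig_length < contig_gate_factor * target_insert
  ok_orient <- pairs$orientation == expected_orientation
  ok_mapq <- pairs$mapq1 >= min_mapq & pairs$mapq2 >= min_mapq
  used <- same & !gate_contig & ok_orient & ok_mapq

  n_gate <- sum(gate_contig)
  n_other <- sum(!used) - n_gate
  if (!any(used)) {
    stop("no usable pairs: ", n_gate, " rejected by the contig-length gate, ",
         sum(!same), " on different contigs, ",
         sum(same & !ok_orient), " wrong orientation, ",
         sum(same & ok_orient & !ok_mapq), " low mapping quality")
  }
  p <- pairs[used, , drop = FALSE]
  ins <- pmax(p$pos1 + p$read_len1, p$pos2 + p$read_len2) -
    pmin(p$pos1, p$pos2)
  med <- stats::median(ins)
  dev <- stats::mad(ins)
  keep <- if (dev == 0) rep(TRUE, length(ins)) else
    abs(ins - med) <= mad_multiplier * dev
  ins_kept <- ins[keep]
  out <- list(
    mean = mean(ins_kept),
    sd = stats::sd(ins_kept),
    median = stats::median(ins_kept),
    n_used = length(ins_kept),
    n_rejected_by_contig_gate = n_gate,
    n_rejected_other = n_other,
    n_outliers_removed = sum(!keep),
    inserts = ins_kept
  )
  if (length(ins_kept) == 1L) out$sd <- 0
  class(out) <- "insert_size_estimate"
  out
}

#' @export
print.insert_size_estimate <- function(x, ...) {
  cat(sprintf("insert size: mean %.1f bp, sd %.1f bp, median %.1f bp (n = %d)\n",
              x$mean, x$sd, x$median, x$n_used))
  cat("  rejected by contig gate:", x$n_rejected_by_contig_gate,
      "| other gates:", x$n_rejected_other,
      "| MAD outliers:", x$n_outliers_removed, "\n")
  invisible(x)
}
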