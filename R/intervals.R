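#' Repeat-mask intervals
#'
#' Per-sequence sorted, non-overlapping intervals in 0-based half-open
#' coordinates — the internal convention for every coordinate in this
#' package. BED input (also 0-based half-open) maps onto it directly;
#' overlapping or book-ended input intervals are merged on construction.
#'
#' @param chrom character vector of sequence names.
#' @param start,end integer vectors, 0-based half-open (`start < end`).
#' @return a `mask_intervals` object: data.frame with columns
#'   `chrom`, `start`, `end`.
#' @export
mask_intervals <- function(chrom = character(0), start = integer(0),
                           end = integer(0)) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("negative interval start")
  bad <- which(start >= end)
  if (length(bad)) {
    stop("interval with start >= end at row ", bad[1],
         " (", chrom[bad[1]], ":", start[bad[1]], "-", end[bad[1]], ")")
  }
  if (length(chrom)) {
    # merge via IRanges::reduce; closed 1-based internally, so +1 on start.
    merged <- lapply(split(seq_along(chrom), chrom), function(idx) {
      ir <- IRanges::reduce(IRanges::IRanges(start = start[idx] + 1,
                                             end = end[idx]))
      data.frame(chrom = chrom[idx][1],
                 start = IRanges::start(ir) - 1,
                 end = IRanges::end(ir),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, merged)
    rownames(out) <- NULL
  } else {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  }
  structure(out, class = c("mask_intervals", "data.frame"))
}

#' @export
print.mask_intervals <- function(x, ...) {
  cat("mask_intervals:", nrow(x), "intervals on",
      length(unique(x$chrom)), "sequences;",
      format(masked_length(x), big.mark = ","), "bp masked\n")
  invisible(x)
}

#' Read a BED3+ file of mask intervals
#'
#' Only the first three columns are used; intervals are merged (overlap or
#' book-ending) per sequence on load.
#'
#' @param path path to a BED file (0-based half-open, as BED is defined).
#' @return a [mask_intervals()] object.
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0L) return(mask_intervals())
  fields <- strsplit(lines, "\t| +")
  nf <- lengths(fields)
  if (any(nf < 3L)) stop("BED line ", which(nf < 3L)[1], " has fewer than 3 columns")
  chrom <- vapply(fields, `[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("non-numeric BED coordinate at line ",
         which(is.na(start) | is.na(end))[1])
  }
  mask_intervals(chrom, start, end)
}

#' Write mask intervals as BED3
#'
#' @param mask a [mask_intervals()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(mask, path) {
  writeLines(sprintf("%s\t%d\t%d", mask$chrom, as.integer(mask$start),
                     as.integer(mask$end)), path)
  invisible(path)
}

#' Total masked length
#'
#' @param mask a [mask_intervals()] object.
#' @return total bp covered by the (already merged) intervals.
#' @export
masked_length <- function(mask) {
  if (nrow(mask) == 0L) return(0)
  sum(mask$end - mask$start)
}

#' Test positions for mask membership
#'
#' Half-open membership: position `p` is masked iff some interval has
#' `start <= p < end` on the same sequence.
#'
#' @param mask a [mask_intervals()] object.
#' @param chrom character vector of sequence names.
#' @param pos numeric vector of 0-based positions.
#' @return logical vector.
#' @export
in_mask <- function(mask, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  out <- logical(length(pos))
  if (nrow(mask) == 0L || length(pos) == 0L) return(out)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    m <- mask[mask$chrom == ch, , drop = FALSE]
    if (nrow(m) == 0L) next
    # intervals are sorted and disjoint: findInterval on starts suffices
    idx <- findInterval(pos[sel], m$start)
    hit <- idx >= 1L & pos[sel] < m$end[pmax(idx, 1L)]
    out[sel] <- hit
  }
  out
}
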