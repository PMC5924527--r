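#' Scaffold set
#'
#' Lengths and N-base counts of an assembly's scaffolds.
#'
#' @param id character vector of scaffold names.
#' @param length numeric vector of lengths (bp, > 0).
#' @param n_count numeric vector of N-base counts (defaults to 0).
#' @return a `scaffold_set` data.frame.
#' @export
scaffold_set <- function(id, length, n_count = 0) {
  stopifnot(all(length > 0), all(n_count <= length), all(n_count >= 0))
  out <- data.frame(id = as.character(id), length = as.numeric(length),
                    n_count = rep_len(as.numeric(n_count), base::length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("scaffold_set", "data.frame")
  out
}

#' Load a scaffold set from FASTA
#'
#' @param path path to a scaffold/contig FASTA file.
#' @return a [scaffold_set()] with per-scaffold lengths and counts of
#'   literal N/n bases.
#' @export
read_scaffolds <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ncount <- Biostrings::letterFrequency(x, "N")[, 1]
  scaffold_set(sub("\\s.*$", "", names(x)), Biostrings::width(x), ncount)
}

#' Nx / Lx assembly statistics
#'
#' Sort lengths descending; Nx is the length at which the cumulative sum
#' first reaches x% of the total, Lx the number of sequences up to and
#' including it.
#'
#' @param lengths numeric vector of scaffold lengths.
#' @param x percentage threshold (default 50).
#' @return list with `Nx` (bp) and `Lx` (count).
#' @export
nx_lx <- function(lengths, x = 50) {
  if (length(lengths) == 0L) stop("empty length set")
  stopifnot(x > 0, x <= 100)
  s <- sort(lengths, decreasing = TRUE)
  i <- which(cumsum(s) >= x / 100 * sum(s))[1]
  list(Nx = s[i], Lx = i)
}

#' Drop scaffolds below a final length cutoff
#'
#' Scaffolds shorter than the shortest informative read are assembly
#' artifacts; the cutoff is inclusive (a scaffold exactly at the cutoff is
#' kept).
#'
#' @param scaffolds a [scaffold_set()].
#' @param min_final_length minimum kept length in bp (default 250).
#' @return the filtered `scaffold_set`, with attributes `removed_count`
#'   and `removed_bp`.
#' @export
filter_short <- function(scaffolds, min_final_length = 250) {
  keep <- scaffolds$length >= min_final_length
  out <- scaffolds[keep, , drop = FALSE]
  class(out) <- c("scaffold_set", "data.frame")
  attr(out, "removed_count") <- sum(!keep)
  attr(out, "removed_bp") <- sum(scaffolds$length[!keep])
  out
}

#' Assembly statistics at several length cutoffs
#'
#' One row per cutoff, each computed on the subset of scaffolds at least
#' that long — the layout assembly reports use to show how metrics respond
#' to minimum-length filtering.
#'
#' @param scaffolds a [scaffold_set()].
#' @param length_cutoffs ascending bp cutoffs (default
#'   `c(0, 100, 250, 500, 1000)`).
#' @return data.frame with columns `cutoff`, `count`, `total_length`,
#'   `longest`, `n50`, `l50`, `Ns`.
#' @export
stats_table <- function(scaffolds, length_cutoffs = c(0, 100, 250, 500, 1000)) {
  stopifnot(!is.unsorted(length_cutoffs))
  rows <- lapply(length_cutoffs, function(cut) {
    sub <- scaffolds[scaffolds$length >= cut, , drop = FALSE]
    if (nrow(sub) == 0L) {
      return(data.frame(cutoff = cut, count = 0L, total_length = 0,
                        longest = NA_real_, n50 = NA_real_, l50 = NA_integer_,
                        Ns = 0))
    }
    nl <- nx_lx(sub$length, 50)
    data.frame(cutoff = cut, count = nrow(sub),
               total_length = sum(sub$length), longest = max(sub$length),
               n50 = nl$Nx, l50 = nl$Lx, Ns = sum(sub$n_count))
  })
  do.call(rbind, rows)
}

#' Percentage with half-up rounding
#'
#' `100 * part / whole`, rounded half away from zero at the requested
#' number of decimals — the rounding convention completeness reports
#' (CEGMA/BUSCO-style) print.
#'
#' @param part,whole counts with `0 <= part <= whole`, `whole > 0`.
#' @param decimals decimal places (default 2).
#' @return the percentage as a plain number.
#' @export
percent_report <- function(part, whole, decimals = 2L) {
  if (any(whole <= 0)) stop("whole must be positive")
  stopifnot(all(part >= 0), all(part <= whole))
  round_half_up(100 * part / whole, decimals)
}

#' Per-class repeat fractions of an assembly
#'
#' @param class_lengths named numeric vector: masked bp per repeat class.
#' @param assembly_length total assembly length in bp.
#' @param decimals decimal places (default 2).
#' @return named numeric vector of percentages.
#' @export
repeat_fraction_table <- function(class_lengths, assembly_length,
                                  decimals = 2L) {
  stopifnot(assembly_length > 0)
  if (any(class_lengths > assembly_length)) {
    stop("repeat class longer than the assembly")
  }
  round_half_up(100 * class_lengths / assembly_length, decimals)
}
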