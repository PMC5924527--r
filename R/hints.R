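#' Hint truncation policy
#'
#' How far each aligned CDS fragment is cut back on both sides before being
#' used as a gene-prediction hint, by evidence class and hit rank. Alignment
#' boundaries are least reliable at fragment edges, and more so for weaker
#' (secondary) hits and cross-species protein alignments than for
#' same-genus transcript alignments — hence the asymmetric defaults:
#' protein top 3 bp, protein secondary 9 bp, transcript top 0 bp,
#' transcript secondary 3 bp, per side.
#'
#' @param cut_bp named numeric vector over
#'   `c("PROTEIN.TOP", "PROTEIN.SECONDARY", "TRANSCRIPT.TOP",
#'   "TRANSCRIPT.SECONDARY")`: bp removed from each side.
#' @param max_hits_per_query total hits kept per query, top hit included
#'   (default 3).
#' @param min_segment_after_cut minimum surviving segment length (default 1).
#' @param codon_multiple_cuts round protein-evidence cuts up to a multiple
#'   of 3 (default FALSE: cuts applied literally in bp).
#' @return a `hint_policy`.
#' @export
hint_policy <- function(cut_bp = c(PROTEIN.TOP = 3, PROTEIN.SECONDARY = 9,
                                   TRANSCRIPT.TOP = 0,
                                   TRANSCRIPT.SECONDARY = 3),
                        max_hits_per_query = 3L,
                        min_segment_after_cut = 1L,
                        codon_multiple_cuts = FALSE) {
  stopifnot(all(cut_bp >= 0), max_hits_per_query >= 1L)
  structure(list(cut_bp = cut_bp,
                 max_hits_per_query = as.integer(max_hits_per_query),
                 min_segment_after_cut = as.integer(min_segment_after_cut),
                 codon_multiple_cuts = isTRUE(codon_multiple_cuts)),
            class = "hint_policy")
}

#' Homology hits
#'
#' Tabular container for ranked alignment hits. `cds_segments` holds, per
#' hit, a data.frame of 0-based half-open `(start, end)` target intervals.
#'
#' @param query_id,target_contig,strand,score,evidence parallel vectors.
#' @param cds_segments list of data.frames with columns `start`, `end`.
#' @return a `homology_hits` data.frame (list-column `cds_segments`).
#' @export
homology_hits <- function(query_id, target_contig, strand, score, evidence,
                          cds_segments) {
  stopifnot(all(evidence %in% c("PROTEIN", "TRANSCRIPT")),
            all(strand %in% c("+", "-")),
            length(cds_segments) == length(query_id))
  out <- data.frame(query_id = query_id, target_contig = target_contig,
                    strand = strand, score = as.numeric(score),
                    evidence = evidence, rank = NA_character_,
                    stringsAsFactors = FALSE)
  out$cds_segments <- cds_segments
  class(out) <- c("homology_hits", "data.frame")
  out
}

#' Read homology hits from tabular files
#'
#' Expected columns (TSV): query, target, strand, score, segments — the
#' last a comma-separated list of `start-end` 0-based half-open spans.
#'
#' @param path path to the hit table.
#' @param evidence "PROTEIN" or "TRANSCRIPT" for all hits in the file.
#' @return a [homology_hits()] table.
#' @export
read_hits_tsv <- function(path, evidence = c("PROTEIN", "TRANSCRIPT")) {
  evidence <- match.arg(evidence)
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("query", "target", "strand",
                                        "score", "segments"))
  segs <- lapply(strsplit(df$segments, ",", fixed = TRUE), function(ss) {
    parts <- strsplit(ss, "-", fixed = TRUE)
    data.frame(start = as.numeric(vapply(parts, `[`, character(1), 1L)),
               end = as.numeric(vapply(parts, `[`, character(1), 2L)))
  })
  homology_hits(df$query, df$target, df$strand, df$score,
                rep(evidence, nrow(df)), segs)
}

#' Rank hits per query and drop the surplus
#'
#' Per query: hits are sorted by score descending (ties broken by longer
#' summed segment length, then leftmost target start, then target contig
#' id), the best hit ranked `TOP`, the next up to
#' `max_hits_per_query - 1` ranked `SECONDARY`, and the rest dropped.
#'
#' @param hits a [homology_hits()] table.
#' @param policy a [hint_policy()].
#' @return the ranked table (dropped hits removed), ordered by query.
#' @export
rank_hits <- function(hits, policy = hint_policy()) {
  seg_len <- vapply(hits$cds_segments,
                    function(s) sum(s$end - s$start), numeric(1))
  seg_start <- vapply(hits$cds_segments,
                      function(s) if (nrow(s)) min(s$start) else Inf,
                      numeric(1))
  ord <- order(hits$query_id, -hits$score, -seg_len, seg_start,
               hits$target_contig)
  hits <- hits[ord, , drop = FALSE]
  idx <- stats::ave(seq_len(nrow(hits)), hits$query_id, FUN = seq_along)
  hits$rank <- ifelse(idx == 1L, "TOP", "SECONDARY")
  hits <- hits[idx <= policy$max_hits_per_query, , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("homology_hits", "data.frame")
  hits
}

#' Truncate a hit's CDS segments by its evidence class and rank
#'
#' Each segment `(s, e)` becomes `(s + c, e - c)` where `c` is the policy's
#' per-side cut for the hit's evidence/rank; segments whose trimmed length
#' falls below `min_segment_after_cut` are dropped.
#'
#' @param hit one row of a ranked [homology_hits()] table.
#' @param policy a [hint_policy()].
#' @return list with `segments` (data.frame start/end) and `dropped`
#'   (count of over-trimmed segments).
#' @export
truncate_segments <- function(hit, policy = hint_policy()) {
  if (is.na(hit$rank)) stop("hit has no rank; run rank_hits() first")
  cut <- policy$cut_bp[[paste(hit$evidence, hit$rank, sep = ".")]]
  if (policy$codon_multiple_cuts && hit$evidence == "PROTEIN") {
    cut <- 3 * ceiling(cut / 3)
  }
  seg <- hit$cds_segments[[1]]
  s <- seg$start + cut
  e <- seg$end - cut
  keep <- (e - s) >= policy$min_segment_after_cut
  list(segments = data.frame(start = s[keep], end = e[keep]),
       dropped = sum(!keep))
}

#' Cluster truncated segments into hints
#'
#' Single-linkage merge of strictly overlapping segments per
#' contig/strand/evidence; half-open abutment (`end == start`) does not
#' merge. Each output hint spans the union of its members and records how
#' many segments support it.
#'
#' @param segments data.frame with columns `contig`, `strand`, `evidence`,
#'   `start`, `end` (0-based half-open).
#' @return a `hint_set` data.frame: `contig`, `strand`, `evidence`,
#'   `start`, `end`, `support_count`, sorted by contig/strand/start.
#' @export
cluster_hints <- function(segments) {
  if (nrow(segments) == 0L) {
    out <- data.frame(contig = character(0), strand = character(0),
                      evidence = character(0), start = numeric(0),
                      end = numeric(0), support_count = integer(0))
    class(out) <- c("hint_set", "data.frame")
    return(out)
  }
  key <- paste(segments$contig, segments$strand, segments$evidence,
               sep = "\r")
  merged <- lapply(split(seq_len(nrow(segments)), key), function(idx) {
    ir <- IRanges::IRanges(start = segments$start[idx] + 1,
                           end = segments$end[idx])
    # min.gapwidth = 0: merge strict overlaps only, keep abutting apart
    red <- IRanges::reduce(ir, min.gapwidth = 0L, with.revmap = TRUE)
    data.frame(contig = segments$contig[idx][1],
               strand = segments$strand[idx][1],
               evidence = segments$evidence[idx][1],
               start = IRanges::start(red) - 1,
               end = IRanges::end(red),
               support_count = lengths(S4Vectors::mcols(red)$revmap),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$contig, out$strand, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hint_set", "data.frame")
  out
}

#' Build hints from raw hits
#'
#' Convenience pipeline: rank, truncate, pool, cluster.
#'
#' @param hits a [homology_hits()] table.
#' @param policy a [hint_policy()].
#' @return a `hint_set` (see [cluster_hints()]).
#' @export
build_hints <- function(hits, policy = hint_policy()) {
  ranked <- rank_hits(hits, policy)
  pooled <- lapply(seq_len(nrow(ranked)), function(i) {
    tr <- truncate_segments(ranked[i, , drop = FALSE], policy)
    if (nrow(tr$segments) == 0L) return(NULL)
    data.frame(contig = ranked$target_contig[i], strand = ranked$strand[i],
               evidence = ranked$evidence[i], start = tr$segments$start,
               end = tr$segments$end, stringsAsFactors = FALSE)
  })
  pooled <- do.call(rbind, pooled)
  if (is.null(pooled)) {
    pooled <- data.frame(contig = character(0), strand = character(0),
                         evidence = character(0), start = numeric(0),
                         end = numeric(0))
  }
  cluster_hints(pooled)
}

#' Write hints as GFF3 for a gene predictor
#'
#' CDSpart features with `src`/`grp`/`pri` attributes in the dialect
#' AUGUSTUS-style hint files use; protein evidence gets `src=P`, transcript
#' evidence `src=E`.
#'
#' @param hints a `hint_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hints_gff3 <- function(hints, path) {
  lines <- "##gff-version 3"
  if (nrow(hints)) {
    src <- ifelse(hints$evidence == "PROTEIN", "P", "E")
    lines <- c(lines, sprintf(
      "%s\t%s\tCDSpart\t%d\t%d\t.\t%s\t.\tsrc=%s;mult=%d;pri=4",
      hints$contig, "genomeprep",
      as.integer(hints$start + 1), as.integer(hints$end),
      hints$strand, src, as.integer(hints$support_count)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Retain genes supported by both evidence kinds
#'
#' The both-evidence rule: a predicted gene is kept only if it overlaps a
#' hint *and* has a hit in a protein database; everything else is
#' discarded.
#'
#' @param genes data.frame with columns `gene_id`, `has_hint_support`,
#'   `has_db_hit` (logical flags computed upstream).
#' @return list with `kept` (gene ids), `discarded_no_hint`,
#'   `discarded_no_db`, `discarded_neither` (counts).
#' @export
retain_genes <- function(genes) {
  keep <- genes$has_hint_support & genes$has_db_hit
  list(kept = genes$gene_id[keep],
       discarded_no_hint = sum(!genes$has_hint_support & genes$has_db_hit),
       discarded_no_db = sum(genes$has_hint_support & !genes$has_db_hit),
       discarded_neither = sum(!genes$has_hint_support & !genes$has_db_hit))
}
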