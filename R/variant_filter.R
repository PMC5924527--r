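#' Hard-filter policy for called variants
#'
#' GATK-style per-site hard thresholds, with separate rule sets for SNPs
#' and indels. All inequalities are strict, exactly as keep conditions:
#' SNPs pass when `QD > 2`, `FS < 20`, `MQ > 40`, `MQRankSum > -12.5` and
#' `ReadPosRankSum > -8`; indels when `QD > 2`, `FS < 20` and
#' `ReadPosRankSum > -20`. The FS bound is applied as the keep condition
#' `FS < 20` — considerably tighter than the customary `FS > 60` fail
#' threshold — by design. A record lacking an annotation passes that rule
#' by default (rank-sum annotations are undefined at homozygous sites);
#' set `missing_annotation_passes = FALSE` to fail instead.
#'
#' @param snp_rules,indel_rules named lists mapping annotation to
#'   `list(op, threshold)` with `op` one of `">"`, `"<"`.
#' @param missing_annotation_passes logical (default TRUE).
#' @return a `filter_policy`.
#' @export
filter_policy <- function(
    snp_rules = list(QD = list(">", 2.0), FS = list("<", 20.0),
                     MQ = list(">", 40.0), MQRankSum = list(">", -12.5),
                     ReadPosRankSum = list(">", -8.0)),
    indel_rules = list(QD = list(">", 2.0), FS = list("<", 20.0),
                       ReadPosRankSum = list(">", -20.0)),
    missing_annotation_passes = TRUE) {
  structure(list(snp_rules = snp_rules, indel_rules = indel_rules,
                 missing_annotation_passes = isTRUE(missing_annotation_passes)),
            class = "filter_policy")
}

#' Apply hard-filter rules to variants
#'
#' Pure predicate over each record: the SNP or indel rule set is chosen by
#' `vtype` and every rule evaluated with its strict inequality. The result
#' lists the failed rule names per record (empty = pass).
#'
#' @param variants a `variant_set` (from [read_vcf_min()] or
#'   [sim_variants()]).
#' @param policy a [filter_policy()].
#' @return list with logical `pass` and `failed` (list of character
#'   vectors of failed rule names per record).
#' @export
hard_filter <- function(variants, policy = filter_policy()) {
  n <- nrow(variants)
  failed <- vector("list", n)
  for (i in seq_len(n)) failed[[i]] <- character(0)
  for (vt in c("SNP", "INDEL")) {
    rules <- if (vt == "SNP") policy$snp_rules else policy$indel_rules
    rows <- which(variants$vtype == vt)
    if (!length(rows)) next
    for (rule in names(rules)) {
      op <- rules[[rule]][[1]]
      thr <- rules[[rule]][[2]]
      val <- variants[[rule]][rows]
      ok <- if (op == ">") val > thr else val < thr
      ok[is.na(val)] <- policy$missing_annotation_passes
      bad <- rows[!ok]
      for (i in bad) failed[[i]] <- c(failed[[i]], rule)
    }
  }
  list(pass = lengths(failed) == 0L, failed = failed)
}

#' Remove variants inside repeat-mask intervals
#'
#' Membership is tested on the variant start position only (half-open:
#' a variant at the interval end coordinate is kept).
#'
#' @param variants a `variant_set`.
#' @param mask a [mask_intervals()] object.
#' @return list with `kept` (a `variant_set`), `removed` (count).
#' @export
subtract_masked <- function(variants, mask) {
  hit <- in_mask(mask, variants$contig, variants$pos)
  kept <- variants[!hit, , drop = FALSE]
  attr(kept, "header") <- attr(variants, "header")
  class(kept) <- c("variant_set", "data.frame")
  list(kept = kept, removed = sum(hit))
}

#' Zygosity summary per variant type
#'
#' @param variants a `variant_set` with genotypes.
#' @param decimals decimals for the homozygous percentage (default 2).
#' @return data.frame with one row per variant type present: `vtype`,
#'   `total`, `hom_alt`, `het`, `percent_hom`. Types with no records are
#'   absent, not reported as 0%.
#' @export
zygosity_summary <- function(variants, decimals = 2L) {
  types <- intersect(c("SNP", "INDEL"), unique(variants$vtype))
  rows <- lapply(types, function(vt) {
    v <- variants[variants$vtype == vt, , drop = FALSE]
    hom <- sum(v$genotype == "HOM_ALT")
    het <- sum(v$genotype == "HET")
    data.frame(vtype = vt, total = nrow(v), hom_alt = hom, het = het,
               percent_hom = percent_report(hom, nrow(v), decimals),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Heterozygous variant density per kbp
#'
#' `het_count / (unmasked_bp / 1000)` per variant type. The unmasked
#' denominator is an explicit input: supply the genome span over which
#' variants could have been called (typically assembly length minus the
#' repeat-masked length), never derived silently.
#'
#' @param variants a `variant_set`.
#' @param unmasked_bp callable (non-masked) genome length in bp.
#' @param decimals decimals for the density (default 4).
#' @return data.frame with `vtype`, `het`, `density_per_kbp`.
#' @export
het_density <- function(variants, unmasked_bp, decimals = 4L) {
  if (unmasked_bp <= 0) stop("unmasked_bp must be positive")
  types <- intersect(c("SNP", "INDEL"), unique(variants$vtype))
  rows <- lapply(types, function(vt) {
    het <- sum(variants$vtype == vt & variants$genotype == "HET")
    data.frame(vtype = vt, het = het,
               density_per_kbp = round_half_up(het / (unmasked_bp / 1000),
                                               decimals),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
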