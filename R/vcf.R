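#' Minimal VCF reader for hard-filter workflows
#'
#' Parses the subset of VCF 4.x the variant-filter module needs: CHROM, POS,
#' REF, ALT, the INFO annotations `QD`, `FS`, `MQ`, `MQRankSum`,
#' `ReadPosRankSum`, and the GT field of a single sample. Positions are
#' converted to 0-based on input (and back to 1-based on output). All other
#' fields (ID, QUAL, FILTER, the full INFO string, FORMAT, sample) are kept
#' as opaque text so that `write_vcf_min(read_vcf_min(x))` reproduces the
#' records byte-for-byte. An INFO key that is absent from a record is stored
#' as `NA` ("annotation missing"), never as zero.
#'
#' @param path path to a VCF file.
#' @return a `variant_set`: data.frame with columns `contig`, `pos`
#'   (0-based), `ref`, `alt`, `vtype` ("SNP" or "INDEL"), `genotype`
#'   ("HOM_REF", "HET", "HOM_ALT"), numeric columns `QD`, `FS`, `MQ`,
#'   `MQRankSum`, `ReadPosRankSum` (NA when absent), and opaque passthrough
#'   columns; header lines in `attr(,"header")`.
#' @export
read_vcf_min <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0L) {
    return(variant_set_empty(header))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 10L)) {
    stop("VCF record ", which(nf < 10L)[1],
         " has no sample column (need FORMAT + one sample)")
  }
  f <- function(i) vapply(fields, `[`, character(1), i)
  contig <- f(1); pos1 <- f(2); id <- f(3); ref <- toupper(f(4))
  alt <- toupper(f(5)); qual <- f(6); filter <- f(7); info <- f(8)
  format <- f(9); sample <- f(10)
  pos <- suppressWarnings(as.numeric(pos1))
  if (anyNA(pos)) stop("non-numeric POS at VCF record ", which(is.na(pos))[1])

  gt_idx <- vapply(strsplit(format, ":", fixed = TRUE),
                   function(k) match("GT", k), integer(1))
  if (anyNA(gt_idx)) {
    stop("missing GT field at VCF record ", which(is.na(gt_idx))[1])
  }
  gt <- mapply(function(s, i) strsplit(s, ":", fixed = TRUE)[[1]][i],
               sample, gt_idx, USE.NAMES = FALSE)
  genotype <- classify_gt(gt)

  ann <- parse_info_annotations(info)
  vtype <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "INDEL")

  out <- data.frame(contig = contig, pos = pos - 1, id = id, ref = ref,
                    alt = alt, qual = qual, filter = filter, info = info,
                    format = format, sample = sample, vtype = vtype,
                    genotype = genotype, stringsAsFactors = FALSE)
  out <- cbind(out, ann)
  attr(out, "header") <- header
  class(out) <- c("variant_set", "data.frame")
  out
}

variant_set_empty <- function(header = character(0)) {
  out <- data.frame(contig = character(0), pos = numeric(0), id = character(0),
                    ref = character(0), alt = character(0), qual = character(0),
                    filter = character(0), info = character(0),
                    format = character(0), sample = character(0),
                    vtype = character(0), genotype = character(0),
                    QD = numeric(0), FS = numeric(0), MQ = numeric(0),
                    MQRankSum = numeric(0), ReadPosRankSum = numeric(0),
                    stringsAsFactors = FALSE)
  attr(out, "header") <- header
  class(out) <- c("variant_set", "data.frame")
  out
}

# GT string -> zygosity class. Phased separators treated like unphased.
classify_gt <- function(gt) {
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    a <- a[a != "."]
    if (length(a) == 0L) return("HOM_REF")
    if (all(a == "0")) return("HOM_REF")
    if (length(unique(a)) == 1L) return("HOM_ALT")
    if (any(a == "0")) return("HET")
    "HET"
  }, character(1))
}

# Extract the five filter annotations from INFO strings; NA when absent.
parse_info_annotations <- function(info,
                                   keys = c("QD", "FS", "MQ", "MQRankSum",
                                            "ReadPosRankSum")) {
  pairs <- strsplit(info, ";", fixed = TRUE)
  out <- matrix(NA_real_, nrow = length(info), ncol = length(keys),
                dimnames = list(NULL, keys))
  for (i in seq_along(pairs)) {
    kv <- strsplit(pairs[[i]], "=", fixed = TRUE)
    for (p in kv) {
      if (length(p) == 2L && p[1] %in% keys) {
        v <- suppressWarnings(as.numeric(p[2]))
        if (is.na(v)) {
          stop("non-numeric INFO value for ", p[1], " at VCF record ", i,
               ": '", p[2], "'")
        }
        out[i, p[1]] <- v
      }
    }
  }
  as.data.frame(out)
}

#' Write a `variant_set` back to VCF
#'
#' Emits the preserved header and the opaque passthrough fields, converting
#' positions back to 1-based. Records the reader supports round-trip
#' byte-identically.
#'
#' @param variants a `variant_set` from [read_vcf_min()].
#' @param path output path.
#' @param filter optional character vector overriding the FILTER column
#'   (e.g. "PASS" or semicolon-joined failed-rule names).
#' @return `path`, invisibly.
#' @export
write_vcf_min <- function(variants, path, filter = NULL) {
  header <- attr(variants, "header")
  if (is.null(header) || length(header) == 0L) {
    header <- c("##fileformat=VCFv4.2",
                paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", "SAMPLE", sep = "\t"))
  }
  filt <- if (is.null(filter)) variants$filter else filter
  body <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s",
                  variants$contig, format(variants$pos + 1, scientific = FALSE,
                                          trim = TRUE),
                  variants$id, variants$ref, variants$alt, variants$qual,
                  filt, variants$info, variants$format, variants$sample)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x), "records (",
      sum(x$vtype == "SNP"), "SNPs,", sum(x$vtype == "INDEL"), "indels )\n")
  invisible(x)
}
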