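#' Default junction linker used by the simulators
#'
#' A fixed 38-bp non-palindromic stand-in for a Cre-Lox circularisation
#' junction (synthetic; real junction sequences are library-kit specific
#' and supplied by the user in production use).
#'
#' @return a DNA string.
#' @export
default_sim_linker <- function() {
  # 38 bp, not self-reverse-complementary
  "ACTTCGAGCACGTTAAGCCTGGATACGGTCAATTGCGA"
}

#' Simulate a genome with optional internal duplication
#'
#' I.i.d. bases at the requested GC content. When `duplicated_fraction > 0`
#' a contiguous segment of that fraction of the genome is copied over a
#' disjoint region, so the genome carries the segment twice — the
#' structure that produces a 2x multiplicity peak in the k-mer spectrum.
#'
#' @param genome_size genome length in bp (>= 1000).
#' @param duplicated_fraction fraction of the genome present in two copies
#'   (default 0).
#' @param gc GC content (default 0.4).
#' @param seed RNG seed.
#' @return named character vector of length 1 (sequence `"genome"`), with
#'   `attr(,"dup_region")` recording the duplication when present.
#' @export
sim_genome <- function(genome_size, duplicated_fraction = 0, gc = 0.4,
                       seed = 1L) {
  stopifnot(genome_size >= 1000, duplicated_fraction >= 0,
            duplicated_fraction < 0.5, gc > 0, gc < 1)
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    bases <- sample(names(p), genome_size, replace = TRUE, prob = p)
    dup <- NULL
    if (duplicated_fraction > 0) {
      dl <- round(duplicated_fraction * genome_size)
      src <- sample.int(genome_size %/% 2L - dl, 1L)        # source in 1st half
      dst <- genome_size %/% 2L + sample.int(genome_size %/% 2L - dl, 1L)
      bases[dst:(dst + dl - 1L)] <- bases[src:(src + dl - 1L)]
      dup <- c(src_start = src - 1L, dst_start = dst - 1L, length = dl)
    }
    out <- c(genome = paste(bases, collapse = ""))
    attr(out, "dup_region") <- dup
    out
  })
}

#' Simulate shotgun reads from a genome
#'
#' Uniform start positions on both strands, per-base substitution errors at
#' `base_error_rate`, constant qualities encoding that error rate. A
#' `contamination_rate` fraction of reads has an adapter copy overwriting a
#' window at a random position (read-through contamination). Emits a truth
#' table alongside the reads.
#'
#' @param genome character vector from [sim_genome()] (first sequence used).
#' @param coverage target base coverage.
#' @param read_length read length in bp.
#' @param base_error_rate substitution error rate (default 0).
#' @param adapter adapter sequence for contamination (default none).
#' @param contamination_rate fraction of reads contaminated (default 0).
#' @param seed RNG seed.
#' @return list with `reads` (a [read_set()]) and `truth` (data.frame
#'   `id`, `start`, `strand`, `contaminated`).
#' @export
sim_reads <- function(genome, coverage, read_length, base_error_rate = 0,
                      adapter = NULL, contamination_rate = 0, seed = 1L) {
  g <- genome[[1]]
  glen <- nchar(g)
  stopifnot(read_length <= glen, coverage > 0,
            base_error_rate >= 0, base_error_rate < 1)
  n <- round(coverage * glen / read_length)
  with_seed(seed, {
    starts <- sample.int(glen - read_length + 1L, n, replace = TRUE)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- substring(g, starts, starts + read_length - 1L)
    neg <- strands == "-"
    seqs[neg] <- revcomp(seqs[neg])
    seqs <- inject_errors(seqs, base_error_rate)
    contaminated <- logical(n)
    if (!is.null(adapter) && contamination_rate > 0) {
      adapter <- toupper(adapter)
      stopifnot(nchar(adapter) <= read_length)
      contaminated <- stats::runif(n) < contamination_rate
      at <- sample.int(read_length - nchar(adapter) + 1L, sum(contaminated),
                       replace = TRUE)
      seqs[contaminated] <- overwrite_at(seqs[contaminated], adapter, at)
    }
    q <- max(2L, min(40L, round(-10 * log10(max(base_error_rate, 1e-4)))))
    qual <- strrep(intToUtf8(q + 33L), read_length)
    ids <- sprintf("sr%06d", seq_len(n))
    list(reads = read_set(ids, seqs, rep(qual, n)),
         truth = data.frame(id = ids, start = starts - 1L, strand = strands,
                            contaminated = contaminated,
                            stringsAsFactors = FALSE))
  })
}

# Substitute bases at the given per-base rate (never to the original base).
inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in hit) {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Overwrite seqs[i] with `ins` starting at 1-based position at[i].
overwrite_at <- function(seqs, ins, at) {
  il <- nchar(ins)
  paste0(substr(seqs, 1L, at - 1L), ins,
         substring(seqs, at + il, nchar(seqs)))
}

#' Simulate mate pairs with planted junction linkers
#'
#' Pairs are drawn at insert sizes from a normal distribution truncated to
#' `[read_length, genome length]`. Each read independently carries, with
#' probability `linker_fraction`, a read-through junction linker: genuine
#' fragment bases up to a recorded junction position, then the linker, then
#' random filler — the failure mode junction clipping exists for. The
#' truth table records each read's junction position (`NA` = no linker).
#'
#' @param genome character vector from [sim_genome()].
#' @param n_pairs number of pairs.
#' @param insert_mean,insert_sd insert size distribution (bp).
#' @param read_length read length in bp.
#' @param linker linker sequence (default [default_sim_linker()]).
#' @param linker_fraction per-read probability of a read-through junction
#'   (default 0.3).
#' @param seed RNG seed.
#' @return list with `pairs` (a [read_pair_set()]) and `truth`
#'   (data.frame `id`, `junction1`, `junction2`; 0-based positions, NA when
#'   the read has no linker).
#' @export
sim_matepairs <- function(genome, n_pairs, insert_mean, insert_sd,
                          read_length, linker = default_sim_linker(),
                          linker_fraction = 0.3, seed = 1L) {
  g <- genome[[1]]
  glen <- nchar(g)
  stopifnot(insert_mean < glen / 3, read_length < insert_mean)
  linker <- toupper(linker)
  with_seed(seed, {
    ins <- pmin(pmax(round(stats::rnorm(n_pairs, insert_mean, insert_sd)),
                     read_length), glen)
    starts <- vapply(ins, function(i) sample.int(glen - i + 1L, 1L),
                     integer(1))
    # read1: fragment 5' end forward; read2: fragment 3' end reverse strand
    r1 <- substring(g, starts, starts + read_length - 1L)
    r2 <- revcomp(substring(g, starts + ins - read_length, starts + ins - 1L))
    plant <- function(seqs) {
      has <- stats::runif(n_pairs) < linker_fraction
      # junction far enough inside that the kept prefix is informative and
      # the in-read linker span can satisfy the core rule
      pos <- sample(seq(10L, read_length - 10L), n_pairs, replace = TRUE)
      for (i in which(has)) {
        tail_len <- read_length - pos[i]
        fill <- paste(sample(c("A", "C", "G", "T"),
                             max(0L, tail_len - nchar(linker)),
                             replace = TRUE), collapse = "")
        seqs[i] <- paste0(substr(seqs[i], 1L, pos[i]),
                          substr(paste0(linker, fill), 1L, tail_len))
      }
      list(seqs = seqs, junction = ifelse(has, pos, NA_integer_))
    }
    p1 <- plant(r1); p2 <- plant(r2)
    ids <- sprintf("mp%06d", seq_len(n_pairs))
    qual <- strrep("I", read_length)
    pairs <- read_pair_set(read_set(ids, p1$seqs, rep(qual, n_pairs)),
                           read_set(ids, p2$seqs, rep(qual, n_pairs)),
                           library_id = "simMP")
    list(pairs = pairs,
         truth = data.frame(id = ids, junction1 = p1$junction,
                            junction2 = p2$junction,
                            insert = ins, stringsAsFactors = FALSE))
  })
}

#' Simulate pair alignments on a contig and write them as SAM
#'
#' Proper FR pairs at normally distributed insert sizes on a single
#' contig; used to exercise insert-size estimation with known truth.
#'
#' @param contig_length contig length in bp.
#' @param n_pairs number of pairs.
#' @param insert_mean,insert_sd true insert distribution (bp).
#' @param read_length read length (bp).
#' @param mapq mapping quality written for all records (default 60).
#' @param contig_id contig name (default "ctg1").
#' @param seed RNG seed.
#' @return list with `sam` (character vector of SAM lines) and `truth`
#'   (data.frame of drawn inserts).
#' @export
sim_pair_sam <- function(contig_length, n_pairs, insert_mean, insert_sd,
                         read_length = 100L, mapq = 60L,
                         contig_id = "ctg1", seed = 1L) {
  stopifnot(contig_length >= insert_mean)
  with_seed(seed, {
    ins <- pmin(pmax(round(stats::rnorm(n_pairs, insert_mean, insert_sd)),
                     2L * read_length), contig_length)
    start <- vapply(ins, function(i) {
      sample.int(contig_length - i + 1L, 1L)
    }, integer(1))
    p1 <- start                      # 1-based leftmost, forward mate
    p2 <- start + ins - read_length  # reverse mate
    seq_ <- strrep("A", read_length)
    qual <- strrep("I", read_length)
    cg <- paste0(read_length, "M")
    ids <- sprintf("pa%06d", seq_len(n_pairs))
    rec <- function(id, flag, pos, mpos, tlen) {
      sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t%s\t%s",
              id, flag, contig_id, pos, mapq, cg, mpos, tlen, seq_, qual)
    }
    sam <- c(
      "@HD\tVN:1.6\tSO:unsorted",
      sprintf("@SQ\tSN:%s\tLN:%d", contig_id, contig_length),
      as.vector(rbind(rec(ids, 99L, p1, p2, ins),
                      rec(ids, 147L, p2, p1, -ins)))
    )
    list(sam = sam, truth = data.frame(id = ids, insert = ins))
  })
}

#' Simulate annotated variant records with filter ground truth
#'
#' Records get genotypes and the five hard-filter annotations, each drawn
#' on either side of its threshold with the stated probability of passing,
#' so every record's true pass/fail status is known. A fraction of
#' positions falls inside emitted mask intervals.
#'
#' @param n_snp,n_indel record counts.
#' @param contig_length genome span positions are drawn from.
#' @param pass_prob per-rule probability an annotation is drawn on the
#'   passing side (default 0.8).
#' @param hom_fraction fraction of HOM_ALT genotypes (default 0.05).
#' @param masked_fraction fraction of the contig covered by mask
#'   intervals (default 0.2).
#' @param missing_rate probability an annotation is absent (default 0.05).
#' @param seed RNG seed.
#' @return list with `variants` (a `variant_set`), `mask`
#'   ([mask_intervals()]), and `truth` (data.frame with `pass` and
#'   `masked` flags per record).
#' @export
sim_variants <- function(n_snp, n_indel, contig_length = 1e6,
                         pass_prob = 0.8, hom_fraction = 0.05,
                         masked_fraction = 0.2, missing_rate = 0.05,
                         seed = 1L) {
  with_seed(seed, {
    n <- n_snp + n_indel
    vtype <- c(rep("SNP", n_snp), rep("INDEL", n_indel))
    pos <- sort(sample.int(contig_length, n))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    ins <- vtype == "INDEL"
    ref[ins] <- paste0(ref[ins], sample(bases, sum(ins), replace = TRUE))

    draw <- function(op, thr, active) {
      # passing side vs failing side of a strict threshold
      side <- stats::runif(n) < pass_prob
      delta <- stats::runif(n, 0.5, 5)
      v <- if (op == ">") ifelse(side, thr + delta, thr - delta)
           else ifelse(side, thr - delta, thr + delta)
      v[stats::runif(n) < missing_rate] <- NA_real_
      v[!active] <- NA_real_
      round(v, 2)
    }
    snp_active <- !ins
    QD <- draw(">", 2.0, TRUE)
    FS <- draw("<", 20.0, TRUE)
    MQ <- draw(">", 40.0, TRUE)
    MQRankSum <- draw(">", -12.5, snp_active)
    ReadPosRankSum <- draw(">", ifelse(ins, -20.0, -8.0), TRUE)
    # per-record truth under the default policy (missing passes)
    rule_ok <- function(v, op, thr) ifelse(is.na(v), TRUE,
                                           if (op == ">") v > thr else v < thr)
    pass <- rule_ok(QD, ">", 2.0) & rule_ok(FS, "<", 20.0) &
      ifelse(ins, TRUE, rule_ok(MQ, ">", 40.0)) &
      ifelse(ins, TRUE, rule_ok(MQRankSum, ">", -12.5)) &
      rule_ok(ReadPosRankSum, ">", ifelse(ins, -20.0, -8.0))

    genotype <- ifelse(stats::runif(n) < hom_fraction, "HOM_ALT", "HET")
    gt <- ifelse(genotype == "HOM_ALT", "1/1", "0/1")

    # mask: disjoint intervals totalling ~masked_fraction of the contig
    n_iv <- 50L
    iv_len <- round(masked_fraction * contig_length / n_iv)
    iv_start <- sort(sample.int(contig_length - iv_len, n_iv))
    mask <- mask_intervals(rep("ctg1", n_iv), iv_start,
                           pmin(iv_start + iv_len, contig_length))

    fmt_ann <- function(k, v) ifelse(is.na(v), NA_character_,
                                     paste0(k, "=", format(v, trim = TRUE)))
    info <- apply(cbind(fmt_ann("QD", QD), fmt_ann("FS", FS),
                        fmt_ann("MQ", MQ), fmt_ann("MQRankSum", MQRankSum),
                        fmt_ann("ReadPosRankSum", ReadPosRankSum)),
                  1L, function(r) paste(stats::na.omit(r), collapse = ";"))
    info[!nzchar(info)] <- "."

    variants <- data.frame(
      contig = "ctg1", pos = pos - 1, id = ".", ref = ref, alt = alt,
      qual = "100", filter = ".", info = info, format = "GT", sample = gt,
      vtype = vtype, genotype = genotype,
      QD = QD, FS = FS, MQ = MQ, MQRankSum = MQRankSum,
      ReadPosRankSum = ReadPosRankSum, stringsAsFactors = FALSE)
    attr(variants, "header") <- c(
      "##fileformat=VCFv4.2",
      sprintf("##contig=<ID=ctg1,length=%d>", as.integer(contig_length)),
      paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "SAMPLE", sep = "\t"))
    class(variants) <- c("variant_set", "data.frame")
    masked <- in_mask(mask, variants$contig, variants$pos)
    list(variants = variants, mask = mask,
         truth = data.frame(pass = pass, masked = masked))
  })
}
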