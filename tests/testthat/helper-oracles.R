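# Brute-force oracles, independent of the implementation paths they check.

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# total covered length by marking positions in a per-sequence bitmap
oracle_masked_length <- function(chrom, start, end) {
  total <- 0
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    bits <- logical(max(end[sel]))
    for (i in which(sel)) bits[(start[i] + 1):end[i]] <- TRUE
    total <- total + sum(bits)
  }
  total
}

oracle_in_mask <- function(chrom_iv, start_iv, end_iv, chrom, pos) {
  vapply(seq_along(pos), function(i) {
    any(chrom_iv == chrom[i] & start_iv <= pos[i] & pos[i] < end_iv)
  }, logical(1))
}

# dictionary canonical k-mer histogram (string-based)
oracle_kmer_hist <- function(seqs, k) {
  all_kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    km <- substring(s, 1:(n - k + 1), k:n)
    km[!grepl("N", km, fixed = TRUE)]
  }))
  rc <- revcomp(all_kmers)
  canon <- ifelse(all_kmers <= rc, all_kmers, rc)
  mult <- table(canon)
  hist <- table(as.integer(mult))
  data.frame(multiplicity = as.integer(names(hist)),
             count = as.numeric(hist))
}

# exhaustive ungapped linker scorer (all offsets, both strands)
oracle_linker_best <- function(read, config) {
  read <- toupper(read)
  rch <- strsplit(read, "", fixed = TRUE)[[1]]
  rl <- length(rch)
  cands <- list()
  strands <- if (config$search_both_strands) c("+", "-") else "+"
  for (strand in strands) {
    lk <- if (strand == "+") config$linker_sequence else config$linker_rc
    lch <- strsplit(lk, "", fixed = TRUE)[[1]]
    ll <- length(lch)
    for (off in (-(ll - config$min_core)):(rl - config$min_core)) {
      a <- max(0L, off)
      b <- min(rl, off + ll)
      al <- b - a
      if (al < config$min_core) next
      idx <- (a + 1L):b
      eq <- rch[idx] == lch[idx - off] & rch[idx] != "N"
      matches <- sum(eq)
      runs <- rle(eq)
      best_run <- max(c(0L, runs$lengths[runs$values]))
      if (best_run < config$min_core) next
      if (matches < config$min_identity * al) next
      cands[[length(cands) + 1L]] <- list(
        read_start = a, read_end = b, matches = matches,
        aligned_length = al, longest_exact_run = best_run, strand = strand)
    }
  }
  if (!length(cands)) return(NULL)
  sc <- vapply(cands, `[[`, numeric(1), "matches")
  rs <- vapply(cands, `[[`, numeric(1), "read_start")
  st <- vapply(cands, `[[`, character(1), "strand")
  cands[[order(-sc, rs, st != "+")[1]]]
}

# cumulative-scan Nx/Lx
oracle_nx_lx <- function(lengths, x) {
  s <- sort(lengths, decreasing = TRUE)
  cum <- 0
  for (i in seq_along(s)) {
    cum <- cum + s[i]
    if (cum >= x / 100 * sum(s)) return(list(Nx = s[i], Lx = i))
  }
}

# per-record hard-filter predicate, written independently of hard_filter()
oracle_filter_pass <- function(v, missing_passes = TRUE) {
  chk <- function(val, op, thr) {
    if (is.na(val)) return(missing_passes)
    if (op == ">") val > thr else val < thr
  }
  vapply(seq_len(nrow(v)), function(i) {
    if (v$vtype[i] == "SNP") {
      chk(v$QD[i], ">", 2) && chk(v$FS[i], "<", 20) &&
        chk(v$MQ[i], ">", 40) && chk(v$MQRankSum[i], ">", -12.5) &&
        chk(v$ReadPosRankSum[i], ">", -8)
    } else {
      chk(v$QD[i], ">", 2) && chk(v$FS[i], "<", 20) &&
        chk(v$ReadPosRankSum[i], ">", -20)
    }
  }, logical(1))
}
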