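linker <- default_sim_linker()  # 38 bp
cfg <- linker_config(linker)

test_that("a planted exact linker is found at its position with a full run", {
  set.seed(21)
  for (rep in 1:10) {
    read <- paste0(random_dna(20), linker, random_dna(20))
    m <- find_linker(read, cfg)
    expect_false(is.null(m))
    expect_equal(m$read_start, 20)
    expect_equal(m$read_end, 58)
    expect_equal(m$longest_exact_run, 38)
    expect_equal(m$strand, "+")
  }
})

test_that("a reverse-complemented planted linker is found on the - strand", {
  set.seed(22)
  read <- paste0(random_dna(15), revcomp(linker), random_dna(15))
  m <- find_linker(read, cfg)
  expect_equal(m$read_start, 15)
  expect_equal(m$strand, "-")
})

test_that("high identity without a 9-bp continuous core is rejected", {
  # mutate every 8th base: longest exact run is 7-8 bp, identity 34/38 = 0.89
  ch <- strsplit(linker, "")[[1]]
  for (i in seq(8, 38, by = 8)) {
    ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  }
  degraded <- paste(ch, collapse = "")
  set.seed(23)
  read <- paste0(random_dna(20), degraded, random_dna(20))
  oracle <- oracle_linker_best(degraded, cfg)  # sanity: run really < 9
  expect_null(oracle)
  expect_null(find_linker(read, cfg))
  # the identity criterion alone would have accepted it
  expect_false(is.null(find_linker(read, linker_config(linker, min_core = 1))))
})

test_that("linker-free reads yield no match and errors on empty input", {
  set.seed(24)
  expect_null(find_linker(random_dna(100), cfg))
  expect_error(find_linker("", cfg), "empty")
})

test_that("scan agrees with the exhaustive oracle on random and seeded reads", {
  set.seed(25)
  short_linker <- random_dna(20)
  ccfg <- linker_config(short_linker, min_core = 6, min_identity = 0.75)
  for (rep in 1:60) {
    read <- switch(1 + rep %% 3,
      random_dna(sample(30:200, 1)),                                # clean
      paste0(random_dna(sample(5:80, 1)), short_linker,
             random_dna(sample(0:60, 1))),                          # planted
      { # degraded planted copy
        ch <- strsplit(short_linker, "")[[1]]
        k <- sample(0:5, 1)
        if (k > 0) {
          at <- sample(20, k)
          ch[at] <- vapply(ch[at], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        }
        paste0(random_dna(sample(5:50, 1)), paste(ch, collapse = ""),
               random_dna(sample(0:50, 1)))
      })
    got <- find_linker(read, ccfg)
    want <- oracle_linker_best(read, ccfg)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got, want)
    }
  }
})

test_that("raising min_core only removes matches (core-rule monotonicity)", {
  set.seed(26)
  for (rep in 1:40) {
    read <- paste0(random_dna(sample(10:60, 1)),
                   substr(linker, 1, sample(10:38, 1)),
                   random_dna(sample(0:40, 1)))
    strict <- find_linker(read, linker_config(linker, min_core = 9))
    loose <- find_linker(read, linker_config(linker, min_core = 1))
    if (!is.null(strict)) {
      expect_false(is.null(loose))
      expect_gte(loose$matches, strict$matches)
    }
  }
})

test_that("clip_pair categorises pairs and truncates at the linker start", {
  set.seed(27)
  mk <- function(seq) read_set("p", seq, strrep("I", nchar(seq)))
  both <- read_pair_set(mk(paste0(random_dna(40), linker, random_dna(22))),
                        mk(paste0(random_dna(55), linker, random_dna(7))))
  res <- clip_pair(both, cfg)
  expect_equal(as.character(res$category), "BOTH")
  expect_equal(nchar(res$pairs$read1$seq), 40)
  expect_equal(nchar(res$pairs$read2$seq), 55)
  expect_false(res$too_short1 || res$too_short2)

  clean <- read_pair_set(mk(random_dna(100)), mk(random_dna(100)))
  res <- clip_pair(clean, cfg)
  expect_equal(as.character(res$category), "NEITHER")
  expect_equal(res$pairs$read1$seq, clean$read1$seq)
  expect_equal(res$pairs$read2$seq, clean$read2$seq)
})

test_that("kept prefixes below the minimum length are flagged too-short", {
  set.seed(28)
  mk <- function(seq) read_set("p", seq, strrep("I", nchar(seq)))
  pr <- read_pair_set(mk(paste0(random_dna(10), linker, random_dna(52))),
                      mk(random_dna(100)))
  res <- clip_pair(pr, cfg, min_keep = 25)
  expect_equal(as.character(res$category), "READ1_ONLY")
  expect_true(res$too_short1)
  expect_false(res$too_short2)
  expect_equal(nchar(res$pairs$read1$seq), 10)
  # boundary: kept length exactly at min_keep is not flagged
  pr2 <- read_pair_set(mk(paste0(random_dna(25), linker, random_dna(37))),
                       mk(random_dna(100)))
  expect_false(clip_pair(pr2, cfg, min_keep = 25)$too_short1)
})

test_that("clip_pair is idempotent: no qualifying linker survives truncation", {
  g <- sim_genome(20000, seed = 31)
  sim <- sim_matepairs(g, n_pairs = 150, insert_mean = 3000, insert_sd = 300,
                       read_length = 100, linker_fraction = 0.4, seed = 31)
  once <- clip_pair(sim$pairs, cfg)
  twice <- clip_pair(once$pairs, cfg)
  expect_equal(twice$pairs$read1$seq, once$pairs$read1$seq)
  expect_equal(twice$pairs$read2$seq, once$pairs$read2$seq)
  expect_true(all(twice$category == "NEITHER"))
})

test_that("split_454 separates segments, trims and reverse-complements", {
  mkread <- function(seq, qual) read_set("r454", seq, qual)
  # palindromic check case: RC of CCGG is CCGG
  r <- mkread(paste0("AAAA", linker, "CCGG"), strrep("?", 46))  # Q30
  out <- split_454(r, cfg, trim_quality = 20)
  expect_true(out$split)
  expect_equal(out$forward$seq, "AAAA")
  expect_equal(out$reverse_rc$seq, "CCGG")

  # trailing low-quality bases removed before reverse-complementing
  r <- mkread(paste0("AAAA", linker, "ACCTTT"),
              paste0(strrep("?", 46), "##"))  # last two bases Q2
  out <- split_454(r, cfg, trim_quality = 20)
  expect_equal(out$reverse_rc$seq, "AGGT")  # revcomp of the trimmed "ACCT"
  expect_equal(phred(out$reverse_rc, 1), rep(30L, 4))

  # length conservation before trimming
  set.seed(29)
  r <- mkread(paste0(random_dna(30), linker, random_dna(40)), strrep("I", 108))
  out <- split_454(r, cfg)
  span <- out$match$read_end - out$match$read_start
  rev_before_trim <- 108 - out$match$read_end
  expect_equal(nchar(out$forward$seq) + span + rev_before_trim, 108)

  expect_false(split_454(mkread(random_dna(80), strrep("I", 80)), cfg)$split)
})

test_that("adapter dropping removes whole contaminated reads only", {
  adapter <- "AGATCGGAAGAGCACACGTCT"  # 21 bp
  acfg <- adapter_filter_config(adapter, kmer_length = 11,
                                min_terminal_match = 8)
  set.seed(30)
  clean <- vapply(1:50, function(i) random_dna(100), character(1))
  full <- paste0(random_dna(40), adapter, random_dna(39))       # stage 1
  term <- paste0(random_dna(92), substr(adapter, 1, 8))         # stage 2
  reads <- read_set(sprintf("r%02d", 1:52), c(clean, full, term),
                    rep(strrep("I", 100), 52))
  res <- drop_adapter_reads(reads, acfg)
  expect_equal(res$dropped_stage1, 1)
  expect_equal(res$dropped_stage2, 1)
  # kept reads are untouched and adapter-free by the substring oracle
  expect_equal(res$kept$seq, clean)
  expect_false(any(grepl(adapter, res$kept$seq, fixed = TRUE)))
  expect_error(adapter_filter_config(character(0)), "empty")
})

test_that("adapter-free random reads are all kept (zero false positives)", {
  adapter <- "AGATCGGAAGAGCACACGTCT"
  acfg <- adapter_filter_config(adapter)
  set.seed(33)
  seqs <- vapply(1:300, function(i) random_dna(100), character(1))
  # substring oracle: none of these contains an adapter 11-mer or terminal 8-mer
  reads <- read_set(sprintf("r%03d", 1:300), seqs, rep(strrep("I", 100), 300))
  res <- drop_adapter_reads(reads, acfg)
  expect_equal(nrow(res$kept) + res$dropped, 300)
  expect_equal(res$dropped, 0)
})
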