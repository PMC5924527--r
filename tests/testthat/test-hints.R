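seg <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(start = m[, 1], end = m[, 2])
}

test_that("hits are ranked by score with a deterministic tie-break", {
  h <- homology_hits(rep("q1", 4), paste0("t", 1:4), rep("+", 4),
                     c(100, 90, 80, 70), rep("PROTEIN", 4),
                     list(seg(0, 100), seg(0, 100), seg(0, 100), seg(0, 100)))
  r <- rank_hits(h)
  expect_equal(r$rank, c("TOP", "SECONDARY", "SECONDARY"))
  expect_equal(r$score, c(100, 90, 80))  # the 4th hit is dropped

  single <- homology_hits("q1", "t1", "+", 50, "PROTEIN", list(seg(0, 10)))
  expect_equal(rank_hits(single)$rank, "TOP")
})

test_that("ranking equals a brute-force sort oracle on random hits", {
  set.seed(81)
  for (rep in 1:30) {
    n <- sample(1:8, 1)
    segs <- lapply(1:n, function(i) {
      s <- sort(sample.int(1000L, 2)) - 1L
      if (s[1] == s[2]) s[2] <- s[2] + 1L
      seg(s[1], s[2])
    })
    h <- homology_hits(rep("q", n), sample(paste0("t", 1:3), n, replace = TRUE),
                       rep("+", n), sample(1:4, n, replace = TRUE),
                       rep("PROTEIN", n), segs)
    r <- rank_hits(h, hint_policy(max_hits_per_query = 3))
    # oracle: order by (-score, -seglen, start, contig)
    sl <- vapply(segs, function(s) sum(s$end - s$start), numeric(1))
    st <- vapply(segs, function(s) min(s$start), numeric(1))
    ord <- order(-h$score, -sl, st, h$target_contig)
    keep <- ord[seq_len(min(3, n))]
    expect_equal(r$score, h$score[keep])
    expect_equal(r$target_contig, h$target_contig[keep])
    expect_equal(r$rank, c("TOP", rep("SECONDARY", length(keep) - 1)))
  }
})

test_that("truncation cuts per side by evidence class and rank", {
  mk <- function(evidence, rank, s, e) {
    h <- homology_hits("q", "t", "+", 10, evidence, list(seg(s, e)))
    h$rank <- rank
    h
  }
  expect_equal(truncate_segments(mk("PROTEIN", "SECONDARY", 100, 200))$segments,
               seg(109, 191))
  expect_equal(truncate_segments(mk("PROTEIN", "TOP", 100, 200))$segments,
               seg(103, 197))
  expect_equal(truncate_segments(mk("TRANSCRIPT", "TOP", 100, 200))$segments,
               seg(100, 200))
  expect_equal(truncate_segments(mk("TRANSCRIPT", "SECONDARY", 100, 200))$segments,
               seg(103, 197))
  # over-trimmed segments are dropped: 15 bp - 2*9 < 1
  tr <- truncate_segments(mk("PROTEIN", "SECONDARY", 100, 115))
  expect_equal(nrow(tr$segments), 0)
  expect_equal(tr$dropped, 1)
  expect_error(truncate_segments(homology_hits("q", "t", "+", 1, "PROTEIN",
                                               list(seg(0, 10)))), "rank")
})

test_that("truncation shrinks: outputs nest inside inputs, monotone in cut", {
  set.seed(82)
  for (rep in 1:20) {
    s <- sort(sample.int(500L, 2)) - 1L
    if (diff(s) < 1) s[2] <- s[1] + 30L
    h <- homology_hits("q", "t", "+", 1, "PROTEIN", list(seg(s[1], s[2])))
    h$rank <- "TOP"
    cov <- vapply(c(0, 3, 9, 15), function(cut) {
      pol <- hint_policy(cut_bp = c(PROTEIN.TOP = cut, PROTEIN.SECONDARY = cut,
                                    TRANSCRIPT.TOP = cut,
                                    TRANSCRIPT.SECONDARY = cut))
      tr <- truncate_segments(h, pol)$segments
      if (nrow(tr) == 0) return(0)
      expect_gte(tr$start, s[1])
      expect_lte(tr$end, s[2])
      sum(tr$end - tr$start)
    }, numeric(1))
    expect_true(all(diff(cov) <= 0))
  }
})

test_that("hint clustering merges strict overlaps but not abutments", {
  segs <- data.frame(contig = "c", strand = "+", evidence = "PROTEIN",
                     start = c(0, 50), end = c(100, 150))
  h <- cluster_hints(segs)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 0)
  expect_equal(h$end, 150)
  expect_equal(h$support_count, 2)

  abut <- data.frame(contig = "c", strand = "+", evidence = "PROTEIN",
                     start = c(0, 100), end = c(100, 200))
  h2 <- cluster_hints(abut)
  expect_equal(nrow(h2), 2)
  expect_equal(h2$support_count, c(1, 1))
})

test_that("clustering separates contigs, strands and evidence classes", {
  segs <- data.frame(contig = c("c1", "c1", "c1", "c2"),
                     strand = c("+", "-", "+", "+"),
                     evidence = c("PROTEIN", "PROTEIN", "TRANSCRIPT", "PROTEIN"),
                     start = c(0, 0, 0, 0), end = c(100, 100, 100, 100))
  expect_equal(nrow(cluster_hints(segs)), 4)
})

test_that("clustered hints are disjoint, sorted and union-preserving", {
  set.seed(83)
  for (rep in 1:10) {
    n <- 300L
    start <- sample.int(5000L, n, replace = TRUE) - 1L
    len <- sample.int(80L, n, replace = TRUE)
    segs <- data.frame(contig = "c", strand = "+", evidence = "PROTEIN",
                       start = start, end = start + len)
    h <- cluster_hints(segs)
    expect_true(all(diff(h$start) > 0))
    expect_true(all(h$start[-1] >= h$end[-nrow(h)]))
    expect_equal(sum(h$support_count), n)
    # union-of-intervals bitmap oracle
    expect_equal(sum(h$end - h$start),
                 oracle_masked_length(segs$contig, segs$start, segs$end))
  }
})

test_that("build_hints never exceeds raw segment coverage (monotone in cuts)", {
  set.seed(84)
  n <- 40L
  segs <- lapply(1:n, function(i) {
    s <- sample.int(2000L, 1) - 1L
    seg(s, s + sample(30:120, 1))
  })
  h <- homology_hits(sample(paste0("q", 1:10), n, replace = TRUE),
                     sample(paste0("t", 1:2), n, replace = TRUE),
                     sample(c("+", "-"), n, replace = TRUE),
                     stats::runif(n, 1, 100),
                     sample(c("PROTEIN", "TRANSCRIPT"), n, replace = TRUE),
                     segs)
  raw_bp <- sum(vapply(segs, function(s) sum(s$end - s$start), numeric(1)))
  cov <- vapply(c(0, 3, 9), function(cut) {
    pol <- hint_policy(cut_bp = c(PROTEIN.TOP = cut, PROTEIN.SECONDARY = cut,
                                  TRANSCRIPT.TOP = cut,
                                  TRANSCRIPT.SECONDARY = cut))
    hs <- build_hints(h, pol)
    sum(hs$end - hs$start)
  }, numeric(1))
  expect_lte(cov[1], raw_bp)
  expect_true(all(diff(cov) <= 0))
})

test_that("hint tables round-trip from TSV and write valid GFF3", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q1\tctg1\t+\t95.5\t10-50,60-120",
               "q2\tctg2\t-\t80\t0-30"), f)
  h <- read_hits_tsv(f, evidence = "PROTEIN")
  expect_equal(nrow(h), 2)
  expect_equal(h$cds_segments[[1]]$start, c(10, 60))
  hints <- build_hints(h)
  g <- withr::local_tempfile(fileext = ".gff3")
  write_hints_gff3(hints, g)
  lines <- readLines(g)
  expect_equal(lines[1], "##gff-version 3")
  fields <- strsplit(lines[-1], "\t")
  expect_true(all(lengths(fields) == 9))
  starts <- as.numeric(vapply(fields, `[`, character(1), 4))
  ends <- as.numeric(vapply(fields, `[`, character(1), 5))
  expect_true(all(starts >= 1 & starts <= ends))  # 1-based closed on disk
})

test_that("gene retention applies the both-evidence AND rule", {
  g <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                  has_hint_support = c(TRUE, TRUE, FALSE, FALSE),
                  has_db_hit = c(TRUE, FALSE, TRUE, FALSE))
  r <- retain_genes(g)
  expect_equal(r$kept, "g1")
  expect_equal(r$discarded_no_db, 1)
  expect_equal(r$discarded_no_hint, 1)
  expect_equal(r$discarded_neither, 1)
  set.seed(85)
  flags <- data.frame(gene_id = sprintf("g%03d", 1:100),
                      has_hint_support = sample(c(TRUE, FALSE), 100, TRUE),
                      has_db_hit = sample(c(TRUE, FALSE), 100, TRUE))
  expect_equal(retain_genes(flags)$kept,
               flags$gene_id[flags$has_hint_support & flags$has_db_hit])
})
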