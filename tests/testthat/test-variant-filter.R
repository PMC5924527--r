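mkvar <- function(vtype = "SNP", genotype = "HET", QD = NA, FS = NA, MQ = NA,
                  MQRankSum = NA, ReadPosRankSum = NA) {
  v <- data.frame(contig = "c1", pos = 0, ref = "A",
                  alt = if (vtype == "SNP") "T" else "TT",
                  vtype = vtype, genotype = genotype,
                  QD = QD, FS = FS, MQ = MQ, MQRankSum = MQRankSum,
                  ReadPosRankSum = ReadPosRankSum, stringsAsFactors = FALSE)
  class(v) <- c("variant_set", "data.frame")
  v
}

test_that("fully annotated passing and failing SNPs are classified", {
  ok <- mkvar(QD = 3, FS = 5, MQ = 50, MQRankSum = 0, ReadPosRankSum = 0)
  res <- hard_filter(ok)
  expect_true(res$pass)
  expect_length(res$failed[[1]], 0)

  bad <- mkvar(QD = 1.5, FS = 25, MQ = 50, MQRankSum = 0, ReadPosRankSum = 0)
  res <- hard_filter(bad)
  expect_false(res$pass)
  expect_setequal(res$failed[[1]], c("QD", "FS"))
})

test_that("thresholds are strict: values exactly at the bound fail", {
  at_mq <- mkvar(QD = 3, FS = 5, MQ = 40, MQRankSum = 0, ReadPosRankSum = 0)
  res <- hard_filter(at_mq)
  expect_false(res$pass)
  expect_equal(res$failed[[1]], "MQ")
  # every rule at its printed boundary fails
  at_all <- mkvar(QD = 2, FS = 20, MQ = 40, MQRankSum = -12.5,
                  ReadPosRankSum = -8)
  expect_setequal(hard_filter(at_all)$failed[[1]],
                  c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum"))
})

test_that("indels use the reduced rule set without MQ/MQRankSum", {
  v <- mkvar(vtype = "INDEL", QD = 3, FS = 5, MQ = 10, MQRankSum = -30,
             ReadPosRankSum = -15)
  expect_true(hard_filter(v)$pass)  # MQ/MQRankSum not consulted; -15 > -20
  v2 <- mkvar(vtype = "INDEL", QD = 3, FS = 5, ReadPosRankSum = -25)
  expect_equal(hard_filter(v2)$failed[[1]], "ReadPosRankSum")
})

test_that("missing annotations pass by default and fail when configured", {
  v <- mkvar(QD = 3, FS = 5)  # MQ and rank sums absent
  expect_true(hard_filter(v)$pass)
  strict <- filter_policy(missing_annotation_passes = FALSE)
  expect_setequal(hard_filter(v, strict)$failed[[1]],
                  c("MQ", "MQRankSum", "ReadPosRankSum"))
})

test_that("pass set equals the predicate oracle on simulated records", {
  sim <- sim_variants(300, 200, seed = 71)
  res <- hard_filter(sim$variants)
  expect_equal(res$pass, oracle_filter_pass(sim$variants))
  expect_equal(res$pass, sim$truth$pass)  # generator's own truth agrees
  # pure predicate: a permuted batch gives the permuted answers
  set.seed(72)
  perm <- sample.int(nrow(sim$variants))
  shuffled <- sim$variants[perm, , drop = FALSE]
  class(shuffled) <- c("variant_set", "data.frame")
  expect_equal(hard_filter(shuffled)$pass, res$pass[perm])
})

test_that("mask subtraction is half-open on the variant start", {
  m <- mask_intervals("c1", 0, 10)
  inside <- mkvar(); inside$pos <- 5
  at_end <- mkvar(); at_end$pos <- 10
  both <- rbind(inside, at_end)
  class(both) <- c("variant_set", "data.frame")
  res <- subtract_masked(both, m)
  expect_equal(res$removed, 1)
  expect_equal(res$kept$pos, 10)
})

test_that("mask subtraction partitions the input and matches the bitmap", {
  sim <- sim_variants(200, 100, seed = 73)
  res <- subtract_masked(sim$variants, sim$mask)
  expect_equal(nrow(res$kept) + res$removed, 300)
  expect_equal(res$removed, sum(sim$truth$masked))
  oracle <- oracle_in_mask(sim$mask$chrom, sim$mask$start, sim$mask$end,
                           sim$variants$contig, sim$variants$pos)
  expect_equal(sort(res$kept$pos), sort(sim$variants$pos[!oracle]))
})

test_that("zygosity summary reproduces report-style percentages", {
  n_snp <- 3341; hom_snp <- 103
  n_ind <- 1317; hom_ind <- 97
  v <- data.frame(
    contig = "c1", pos = seq_len(n_snp + n_ind), ref = "A",
    alt = c(rep("T", n_snp), rep("TT", n_ind)),
    vtype = c(rep("SNP", n_snp), rep("INDEL", n_ind)),
    genotype = c(rep("HOM_ALT", hom_snp), rep("HET", n_snp - hom_snp),
                 rep("HOM_ALT", hom_ind), rep("HET", n_ind - hom_ind)),
    stringsAsFactors = FALSE)
  class(v) <- c("variant_set", "data.frame")
  z <- zygosity_summary(v)
  expect_equal(z$percent_hom[z$vtype == "SNP"], 3.08)
  expect_equal(z$percent_hom[z$vtype == "INDEL"], 7.37)
  # a type with no records is absent, not 0%
  snps_only <- v[v$vtype == "SNP", ]
  class(snps_only) <- c("variant_set", "data.frame")
  expect_equal(zygosity_summary(snps_only)$vtype, "SNP")
  # all-HET gives 0.00
  allhet <- v; allhet$genotype <- "HET"
  expect_true(all(zygosity_summary(allhet)$percent_hom == 0))
})

test_that("heterozygous densities are per kbp of the supplied denominator", {
  v <- data.frame(
    contig = "c1", pos = seq_len(3341 + 1317), ref = "A",
    alt = c(rep("T", 3341), rep("TT", 1317)),
    vtype = c(rep("SNP", 3341), rep("INDEL", 1317)),
    genotype = c(rep("HOM_ALT", 103), rep("HET", 3341 - 103),
                 rep("HOM_ALT", 97), rep("HET", 1317 - 97)),
    stringsAsFactors = FALSE)
  class(v) <- c("variant_set", "data.frame")
  d <- het_density(v, 138e6)
  expect_equal(d$het, c(3238, 1220))
  expect_equal(d$density_per_kbp[d$vtype == "SNP"], 0.0235)
  expect_equal(d$density_per_kbp[d$vtype == "INDEL"],
               round_half_up(1220 / 138000, 4))
  expect_error(het_density(v, 0), "positive")
  nohet <- v; nohet$genotype <- "HOM_ALT"
  expect_true(all(het_density(nohet, 1e6)$density_per_kbp == 0))
})

test_that("filtering survives a VCF write/read round trip", {
  sim <- sim_variants(80, 40, seed = 74)
  res <- hard_filter(sim$variants)
  filt <- ifelse(res$pass, "PASS",
                 vapply(res$failed, paste, character(1), collapse = ";"))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_min(sim$variants, f, filter = filt)
  back <- read_vcf_min(f)
  expect_equal(hard_filter(back)$pass, res$pass)
  expect_equal(back$filter, filt)
})
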