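test_that("TSV frequency tables round-trip through write/read", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "snp_id\tchrom\tpos\tallele_a\tallele_b\tCEU\tYRI",
    "rs1\t1\t100\tA\tG\t0.050000\t0.200000",
    "rs2\t1\t200\tC\tT\t0.500000\t0.450000",
    "rs3\t2\t300\tG\tA\t0.000000\t1.000000"), tsv)
  tab <- read_frequency_table(tsv)
  expect_s3_class(tab, "freq_table")
  expect_equal(n_snps(tab), 3)
  expect_equal(tab$panels, c("CEU", "YRI"))
  expect_equal(tab$freq["rs1", "CEU"], 0.05)

  out <- tempfile(fileext = ".tsv")
  write_frequency_table(tab, out)
  tab2 <- read_frequency_table(out)
  expect_equal(tab2$freq, round(tab$freq, 6))
  # a second write is byte-identical: printing at 6 decimals is stable
  out2 <- tempfile(fileext = ".tsv")
  write_frequency_table(tab2, out2)
  expect_identical(readLines(out), readLines(out2))
})

test_that("TSV metadata (source, chromosome counts) survives a round trip", {
  tab <- make_table(cbind(P1 = c(0.1, 0.2), P2 = c(0.3, 0.4)))
  tab$chromosomes[] <- c(100L, 120L)
  tab$source <- "estimated"
  path <- tempfile(fileext = ".tsv")
  write_frequency_table(tab, path)
  back <- read_frequency_table(path)
  expect_identical(back$source, "estimated")
  expect_identical(back$chromosomes, c(P1 = 100L, P2 = 120L))
})

test_that("invalid tables are rejected with informative errors", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "snp_id\tchrom\tpos\tallele_a\tallele_b\tCEU",
    "rs1\t1\t100\tA\tG\t1.2"), tsv)
  expect_error(read_frequency_table(tsv), "outside \\[0,1\\].*rs1")

  writeLines(c(
    "snp_id\tchrom\tpos\tallele_a\tallele_b\tCEU",
    "rs1\t1\t100\tA\tG"), tsv)
  expect_error(read_frequency_table(tsv), "line 2")

  snps <- data.frame(snp_id = c("a", "a"), chrom = "1", pos = 1:2,
                     allele_a = "A", allele_b = "G")
  expect_error(freq_table(snps, cbind(P1 = c(0.1, 0.2))), "duplicate")
  snps2 <- data.frame(snp_id = c("a", "b"), chrom = "1", pos = 1:2,
                      allele_a = "A", allele_b = "A")
  expect_error(freq_table(snps2, cbind(P1 = c(0.1, 0.2))), "allele_a")
})

test_that("VCF input yields hand-counted per-panel frequencies", {
  vcf <- write_toy_vcf(tempfile(fileext = ".vcf"))
  tab <- read_frequency_table(vcf, format = "vcf",
                              panel_map = toy_panel_map)
  # rs1: P1 = (2 + 1)/4 REF alleles, P2 = (0 + 1)/4
  expect_equal(tab$freq["rs1", "P1"], 0.75)
  expect_equal(tab$freq["rs1", "P2"], 0.25)
  # rs2: s4 is missing, so P2 denominator is 2 chromosomes
  expect_equal(tab$freq["rs2", "P1"], 1.0)
  expect_equal(tab$freq["rs2", "P2"], 0.5)
  expect_error(
    read_frequency_table(vcf, format = "vcf",
                         panel_map = toy_panel_map[1:3, ]),
    "s4")
  expect_error(read_frequency_table(vcf, format = "vcf"), "panel_map")
})

test_that("founder subsampling is seeded, exact-count and unbiased", {
  set.seed(42)
  n_samp <- 20
  geno <- matrix(rbinom(5 * n_samp, 2, rep(c(0.1, 0.3, 0.5, 0.7, 0.9),
                                           n_samp)),
                 nrow = 5,
                 dimnames = list(NULL, sprintf("s%02d", seq_len(n_samp))))
  gset <- make_genotypes(geno)
  pm <- data.frame(sample = gset$samples, panel = "P1")

  # exactly n_founders samples: no choice, equals the full-panel frequency
  full <- genotype_frequencies(gset, pm)
  sub_all <- subsample_founders(gset, pm, n_founders = n_samp, seed = 1)
  expect_equal(sub_all$freq, full$freq,
               ignore_attr = TRUE, tolerance = 0)

  sub <- subsample_founders(gset, pm, n_founders = 5, seed = 9)
  expect_identical(sub$chromosomes, c(P1 = 10L))
  # frequencies are multiples of 1/(2 * n_founders)
  expect_true(all(abs(sub$freq * 10 - round(sub$freq * 10)) < 1e-12))
  # identical seed => identical table
  sub2 <- subsample_founders(gset, pm, n_founders = 5, seed = 9)
  expect_identical(sub, sub2)
  expect_error(subsample_founders(gset, pm, n_founders = 21, seed = 1),
               "P1")
})

test_that("subsampled frequencies converge to the full-panel frequency", {
  set.seed(7)
  n_samp <- 24
  geno <- matrix(rbinom(n_samp, 2, 0.4), nrow = 1,
                 dimnames = list(NULL, sprintf("s%02d", seq_len(n_samp))))
  gset <- make_genotypes(geno)
  pm <- data.frame(sample = gset$samples, panel = "P1")
  truth <- genotype_frequencies(gset, pm)$freq[1, 1]
  draws <- vapply(seq_len(1000), function(s) {
    subsample_founders(gset, pm, n_founders = 6, seed = s)$freq[1, 1]
  }, 0)
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - truth), 3 * se)
})

test_that("monomorphic flags and stratified counts match enumeration", {
  # 6 SNPs; 2 fixed in panel B (one at 0, one at 1)
  freq <- cbind(CEU = c(0.00, 0.005, 0.03, 0.08, 0.30, 0.50),
                B   = c(0.10, 0.000, 1.00, 0.20, 0.40, 0.50))
  tab <- make_table(freq)
  ann <- annotate_monomorphic(tab)
  expect_equal(sum(ann$flags[, "B"]), 2)
  expect_equal(sum(ann$flags[, "CEU"]), 1)
  expect_true(ann$flags[1, "CEU"])                      # freq 0
  expect_false(ann$flags[2, "CEU"])                     # freq 0.005
  # counts are panel x CEU-MAF-bin; rs2 (CEU maf 0.005) and rs3 (0.03)
  # are the B-monomorphic SNPs
  expect_equal(ann$counts["B", "(0,0.01)"], 1L)
  expect_equal(ann$counts["B", "[0.01,0.05]"], 1L)
  expect_equal(sum(ann$counts["B", ]), 2L)
  expect_equal(unname(ann$counts["CEU", "monomorphic"]), 1L)
})

test_that("polymorphic-in-any filter keeps exactly the segregating records", {
  freq <- cbind(P1 = c(0, 1, 0.0, 0.5, 0.2, 0, 1.0, 0.3, 0.9, 0.00),
                P2 = c(0, 1, 0.6, 0.0, 0.0, 1, 0.4, 0.3, 1.0, 0.01))
  tab <- make_table(freq)
  kept <- filter_polymorphic_any(tab)
  expect_equal(n_snps(kept), 7)  # rows 1, 2 and 6 are fixed everywhere
  expect_false("rs001" %in% kept$snps$snp_id)
  # idempotent
  expect_identical(filter_polymorphic_any(kept), kept)
})

test_that("MAF strata partition [0, 0.5] with the documented conventions", {
  st <- maf_strata("CEU")
  maf <- c(0, 0.0001, 0.009999, 0.01, 0.03, 0.05, 0.050001, 0.1, 0.100001,
           0.5)
  got <- as.character(assign_strata(maf, st))
  expect_equal(got, c("monomorphic", "(0,0.01)", "(0,0.01)", "[0.01,0.05]",
                      "[0.01,0.05]", "[0.01,0.05]", "(0.05,0.1]",
                      "(0.05,0.1]", "(0.1,0.5]", "(0.1,0.5]"))
  expect_false(anyNA(assign_strata(seq(0, 0.5, by = 0.001), st)))
  expect_error(assign_strata(0.6, st), "0.5")
})
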