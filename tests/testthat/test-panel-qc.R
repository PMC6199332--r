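test_that("expected heterozygosity matches closed forms and edge cases", {
  expect_equal(expected_heterozygosity(c(0.95, 0.05)), 0.095)
  expect_equal(expected_heterozygosity(1), 0)
  expect_equal(expected_heterozygosity(rep(0.25, 4)), 0.75)
  expect_error(expected_heterozygosity(numeric(0)), "empty")
  expect_error(expected_heterozygosity(c(0.5, 0.4)), "sum to 1")
})

test_that("H is invariant to allele order and to same-length splitting", {
  f <- c(0.5, 0.3, 0.2)
  expect_equal(expected_heterozygosity(f),
               expected_heterozygosity(rev(f)))
  # splitting the 0.5 class into two same-length sub-alleles, then
  # collapsing, changes nothing
  expect_equal(
    expected_heterozygosity(c(0.2, 0.3, 0.3, 0.2),
                            lengths = c(20, 20, 24, 28)),
    expected_heterozygosity(f))
})

test_that("length-collapsing sums frequencies within length classes", {
  out <- collapse_length_alleles(c(20, 20, 24), c(0.3, 0.2, 0.5))
  expect_equal(out$freq[out$length == 20], 0.5)
  # identity on already length-keyed input
  out2 <- collapse_length_alleles(c(20, 24), c(0.5, 0.5))
  expect_equal(out2$freq, c(0.5, 0.5))
  # 9 sequence alleles over 5 lengths -> exactly 5 output alleles
  lens <- c(10, 10, 12, 12, 12, 14, 16, 18, 18)
  out3 <- collapse_length_alleles(lens, rep(1 / 9, 9))
  expect_equal(nrow(out3), 5)
  expect_equal(sum(out3$freq), 1)
})

test_that("exact binomial HWE test behaves at the centre and tails", {
  f <- c(0.5, 0.5)
  h <- expected_heterozygosity(f)
  n <- 1000
  expect_gte(hwe_het_test(round(n * h), n - round(n * h), f), 0.9)
  expect_lt(hwe_het_test(1000, 0, f), 0.01)   # all calls heterozygous
  expect_equal(hwe_het_test(0, 50, 1), 1)     # monomorphic locus
  # agrees with stats::binom.test as the independent oracle
  for (x in c(430, 500, 572)) {
    expect_equal(hwe_het_test(x, n - x, f),
                 stats::binom.test(x, n, h)$p.value, tolerance = 1e-12)
  }
})

test_that("Mendelian consistency scores quads per the transmission rule", {
  quads <- data.frame(family = "fam1", father = "fa", mother = "mo",
                      child1 = "c1", child2 = "c2")
  gt <- rbind(fa = c(10, 12), mo = c(12, 14), c1 = c(10, 14),
              c2 = c(12, 12))
  expect_equal(mendelian_rate(quads, gt), 1.0)
  gt2 <- rbind(fa = c(10, 10), mo = c(10, 10), c1 = c(10, 12),
               c2 = c(10, 10))
  expect_equal(mendelian_rate(quads, gt2), 0.5)
  # all-hom-ref family leaves the rate undefined, not zero
  gt3 <- rbind(fa = c(0, 0), mo = c(0, 0), c1 = c(0, 0), c2 = c(0, 0))
  expect_true(is.na(mendelian_rate(quads, gt3)))
  expect_error(mendelian_rate(quads, gt[1:3, , drop = FALSE]),
               "unknown sample")
})

test_that("locus filters fire on the documented thresholds", {
  mk_gt <- function(n_called, n_total, freqs, alleles) {
    a <- matrix(sample(alleles, 2 * n_total, TRUE, freqs), ncol = 2)
    if (n_called < n_total) a[(n_called + 1):n_total, ] <- NA
    a
  }
  set.seed(1)
  loci <- data.frame(id = c("low_cr", "maf05", "penta", "hexa"),
                     chrom = "chr1", start = c(100, 5000, 9000, 14000),
                     end = c(120, 5020, 9030, 14030),
                     motif = c("AC", "AC", "ACGTA", "AAAAAT"),
                     period = c(2L, 2L, 5L, 6L),
                     ref_seq = c(NA, NA, "TTAAAAACGT", NA),
                     stringsAsFactors = FALSE)
  gts <- list(mk_gt(79, 100, c(0.5, 0.5), c(0, 2)),
              mk_gt(400, 400, c(0.95, 0.05), c(0, 2)),
              mk_gt(400, 400, c(0.5, 0.5), c(0, 5)),
              mk_gt(400, 400, c(0.5, 0.5), c(0, 6)))
  rep <- apply_locus_filters(loci, gts)
  expect_true(grepl("CALLRATE", rep$filter_flags[1]))
  # pentanucleotide with a 5-base run in the reference sequence fails;
  # hexanucleotide whose longest run is 5 survives (threshold is 6)
  expect_true(grepl("HOMOPOLYMER", rep$filter_flags[3]))
  expect_false(grepl("HOMOPOLYMER", rep$filter_flags[4]))
  # H exactly at the 0.095 boundary passes (threshold is strict <)
  # 400 calls, alt-allele count 40 of 800: MAF exactly 5%
  gts[[2]] <- rbind(matrix(c(0, 0), 365, 2, byrow = TRUE),
                    matrix(c(0, 2), 30, 2, byrow = TRUE),
                    matrix(c(2, 2), 5, 2, byrow = TRUE))
  rep <- apply_locus_filters(loci, gts)
  expect_equal(rep$expected_het[2], 0.095, tolerance = 1e-12)
  expect_false(grepl("LOWHET", rep$filter_flags[2]))
})

test_that("segmental-duplication overlap uses BED half-open coordinates", {
  bed <- data.frame(chrom = "chr1", start0 = 119, end0 = 150)
  loci <- data.frame(id = c("hit", "miss"), chrom = "chr1",
                     start = c(100, 100), end = c(120, 119),
                     motif = "AC", period = 2L, stringsAsFactors = FALSE)
  gt <- matrix(sample(c(0, 2), 200, TRUE), ncol = 2)
  rep <- apply_locus_filters(loci, list(gt, gt), segdup_bed = bed)
  expect_true(grepl("SEGDUP", rep$filter_flags[1]))
  expect_false(grepl("SEGDUP", rep$filter_flags[2]))
})

test_that("malformed BED lines are rejected by line number", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\toops\t30"), p)
  expect_error(read_bed(p), "line 2")
})

test_that("Mendelian rate is 1 on clean quads and decays with stutter", {
  rates <- c(0, 0.08, 0.2)
  means <- sapply(rates, function(e) {
    mean(sapply(1:20, function(s) {
      cfg <- sim_config(n_founder_haplotypes = 40, n_snps = 8,
                        str_mutation_rate = 0.15, stutter_up = e,
                        stutter_down = e, dropout_rate = 0,
                        seed = 200 + s)
      p <- simulate_founder_haplotypes(cfg)
      q <- simulate_quads(p, 30, seed = 300 + s)
      g <- inject_genotyping_errors(q$genotypes, cfg, seed = 400 + s)
      mendelian_rate(q$quads, str_genotype_matrix(g))
    }))
  })
  expect_equal(means[1], 1.0)
  expect_true(all(diff(means) < 0))
})
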