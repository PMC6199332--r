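test_that("transmission phasing recovers transmitted haplotypes", {
  p <- make_panel(seed = 21, n_hap = 60, n_snps = 30, str_mut = 0.15)
  q <- simulate_quads(p, 30, seed = 22, recomb_switch_rate = 0)
  ph <- phase_quads_by_transmission(q$genotypes, q$quads)
  tr <- attr(q$genotypes, "truth")
  res <- attr(ph, "resolution")
  n_ok <- 0; n_tot <- 0
  for (f in seq_len(nrow(q$quads))) {
    for (par in c(q$quads$father[f], q$quads$mother[f])) {
      # truth haplotype transmitted to child1 at that parent's meiosis
      child_col <- if (par == q$quads$father[f]) "H1" else "H2"
      truth_h1 <- tr[[child_col]][q$quads$child1[f], ]
      sites <- which(res[, par] == "transmission")
      het <- sites[ph$A1[par, sites] != ph$A2[par, sites]]
      n_ok <- n_ok + sum(ph$A1[par, het] == truth_h1[het])
      n_tot <- n_tot + length(het)
    }
  }
  expect_gt(n_tot, 100)
  expect_gte(n_ok / n_tot, 0.99)
})

test_that("trivially resolvable sites phase exactly", {
  # all members homozygous: phase is the genotype itself
  sites <- data.frame(id = c("snp1", "str1"), chrom = "chr1",
                      pos = c(100, 5000), type = c("snp", "str"),
                      motif = c(NA, "AC"), period = c(NA, 2L),
                      reflen = c(NA, 20L))
  A <- matrix(c(1, 1, 1, 1, 2, 2, 2, 2), nrow = 4,
              dimnames = list(NULL, NULL))
  g <- strpanel:::new_str_genotypes(sites, A, A,
                                    c("fa", "mo", "c1", "c2"), FALSE)
  quads <- data.frame(family = "fam1", father = "fa", mother = "mo",
                      child1 = "c1", child2 = "c2")
  ph <- phase_quads_by_transmission(g, quads)
  expect_equal(unname(ph$A1[1, ]), c(1, 2))
  expect_true(all(attr(ph, "resolution") == "hom"))
})

test_that("Mendelian-inconsistent sites are set missing and logged", {
  sites <- data.frame(id = c("snp1", "str1"), chrom = "chr1",
                      pos = c(100, 5000), type = c("snp", "str"),
                      motif = c(NA, "AC"), period = c(NA, 2L),
                      reflen = c(NA, 20L))
  # child1 carries an allele neither parent has at the STR
  A1 <- rbind(fa = c(0, 0), mo = c(0, 2), c1 = c(0, 8), c2 = c(0, 0))
  A2 <- rbind(fa = c(1, 0), mo = c(1, 2), c1 = c(1, 8), c2 = c(1, 2))
  g <- strpanel:::new_str_genotypes(sites, A1, A2,
                                    c("fa", "mo", "c1", "c2"), FALSE)
  quads <- data.frame(family = "f", father = "fa", mother = "mo",
                      child1 = "c1", child2 = "c2")
  expect_message(ph <- phase_quads_by_transmission(g, quads),
                 "Mendelian-inconsistent")
  expect_true(all(is.na(ph$A1[, "str1"])))
  expect_gte(attr(ph, "n_mendel_errors"), 1)
})

test_that("panel construction has the quad-design arithmetic", {
  p <- make_panel(seed = 23, n_hap = 40, n_snps = 8)
  q <- simulate_quads(p, 479, seed = 24)
  ph <- phase_quads_by_transmission(q$genotypes, q$quads)
  pan <- build_reference_panel(ph)
  expect_equal(length(unique(pan$samples)), 958)
  expect_equal(nrow(pan$H), 1916)
  expect_false(anyNA(pan$H))
})

test_that("missing STR alleles are filled from the best SNP-matched haplotypes", {
  p <- make_perfect_ld_panel(seed = 25, n_hap = 40, n_snps = 12)
  g <- strpanel:::new_str_genotypes(
    p$sites,
    p$H[seq(1, 39, 2), , drop = FALSE],
    p$H[seq(2, 40, 2), , drop = FALSE],
    unique(p$samples), TRUE)
  sc <- which(g$sites$type == "str")
  truth <- g$A1[3, sc]
  g$A1[3, sc] <- NA  # mask one haplotype's STR allele
  pan <- build_reference_panel(g)
  filled <- pan$H[2 * 3 - 1, sc]
  expect_equal(unname(filled), unname(truth))  # SNP match determines it
})

test_that("imputation copies the STR allele of an identical haplotype", {
  p <- make_panel(seed = 26, n_hap = 50, n_snps = 25, str_mut = 0.2)
  snp_ids <- p$sites$id[p$sites$type == "snp"]
  tgt <- p$H[17, p$sites$type == "snp"]
  names(tgt) <- snp_ids
  res <- impute_str(tgt, p)
  expect_equal(res$score, 0)
  # ties among identical haplotypes resolve within the same SNP class
  expect_true(res$allele %in% panel_str_alleles(p))
  # deterministic given panel + target
  expect_identical(res, impute_str(tgt, p))
})

test_that("a perfectly partitioning SNP yields error-free imputation", {
  p <- make_perfect_ld_panel(seed = 27, n_hap = 60, n_snps = 20)
  snp_ids <- p$sites$id[p$sites$type == "snp"]
  truth <- panel_str_alleles(p)
  for (i in c(1, 10, 33)) {
    tgt <- p$H[i, p$sites$type == "snp"]
    names(tgt) <- snp_ids
    expect_equal(impute_str(tgt, p)$allele, truth[i])
  }
})

test_that("imputation without overlapping SNPs is flagged missing", {
  p <- make_panel(seed = 28, n_hap = 20, n_snps = 5)
  tgt <- c(foo = 1)
  expect_warning(res <- impute_str(tgt, p), "no overlapping SNPs")
  expect_true(is.na(res$allele))
})

test_that("leave-one-out is exact under perfect LD and needs >= 3 samples", {
  p <- make_perfect_ld_panel(seed = 29, n_hap = 60, n_snps = 20)
  loo <- leave_one_out(p)
  pr <- loo_pairs(loo)
  expect_equal(mean(concordance_scores(pr$truth, pr$imputed)), 1.0)
  p2 <- hap_panel(p$sites, p$H[1:4, ], p$samples[1:4])
  expect_error(leave_one_out(p2), ">= 3 samples")
})

test_that("leave-one-out is invariant to panel row order", {
  p <- make_panel(seed = 30, n_hap = 40, n_snps = 20)
  loo1 <- leave_one_out(p)
  # remove a sample and re-add it at the end
  mid <- unique(p$samples)[5]
  keep <- p$samples != mid
  H2 <- rbind(p$H[keep, ], p$H[!keep, ])
  p2 <- hap_panel(p$sites, H2, c(p$samples[keep], p$samples[!keep]))
  loo2 <- leave_one_out(p2)
  o1 <- loo1[order(loo1$sample), ]
  o2 <- loo2[order(loo2$sample), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_identical(o1, o2)
})

test_that("LOO concordance under zero LD sits in the null band", {
  p <- make_panel(seed = 31, n_hap = 160, n_snps = 30, str_mut = 0.3)
  p0 <- permute_str_alleles(p, seed = 32)
  loo <- leave_one_out(p0)
  pr <- loo_pairs(loo)
  ev <- evaluate_locus(pr$truth, pr$imputed)
  band <- range(ev$naive_concordance, ev$random_concordance)
  expect_gte(ev$concordance, band[1] - 0.05)
  expect_lte(ev$concordance, band[2] + 0.05)
})
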