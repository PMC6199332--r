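test_that("genotype scaling hits mean 0, population variance 1", {
  expect_equal(scale_genotype(c(0, 2)), c(-1, 1))
  set.seed(19)
  x <- rnorm(100, 5, 3)
  s <- scale_genotype(x)
  expect_equal(mean(s), 0, tolerance = 1e-12)
  expect_equal(mean(s^2), 1, tolerance = 1e-12)
  expect_equal(scale_genotype(s), s, tolerance = 1e-12)
  expect_error(scale_genotype(rep(1, 5)), "constant")
})

test_that("phenotype simulation honours each generating model", {
  set.seed(20)
  gt <- matrix(sample(c(0, 2, 4), 1000, TRUE), ncol = 2)
  dos <- str_dosage(gt)
  # beta = 1 additive: noise variance 1 - beta = 0, so P = G exactly
  ph <- simulate_phenotype(dos, "additive", beta = 1, seed = 1)
  expect_equal(ph$values, scale_genotype(dos), tolerance = 1e-12)
  expect_error(simulate_phenotype(dos, "additive", beta = 1.2),
               "negative")
  # beta = 0 additive: pure N(0,1) noise
  ph0 <- simulate_phenotype(dos, "additive", beta = 0, seed = 2)
  expect_lt(abs(mean(ph0$values)), 4 / sqrt(500))
  expect_lt(abs(stats::var(ph0$values) - 1), 0.3)
  # beta = 0 case-control: case fraction near 0.5
  cc <- simulate_phenotype(dos, "case_control", beta = 0, seed = 3)
  expect_true(all(cc$values %in% c(0, 1)))
  expect_lt(abs(mean(cc$values) - 0.5), 4 * sqrt(0.25 / 500))
  # quadratic model needs the allele matrix
  expect_error(simulate_phenotype(dos, "quadratic", beta = 0.2),
               "allele matrix")
  phq <- simulate_phenotype(gt, "quadratic", beta = 0.3, seed = 4)
  expect_length(phq$values, 500)
})

test_that("association tests recover exact and null signals", {
  set.seed(21)
  x <- rnorm(100)
  r <- suppressWarnings(association_test(x, x, "linear"))
  expect_lt(r$p_value, 1e-30)
  expect_equal(r$beta_hat, 1, tolerance = 1e-8)
  # permuted phenotypes give uniform p-values
  pvals <- replicate(500, {
    y <- sample(x)
    association_test(x, y, "linear")$p_value
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("logistic separation is flagged as non-converged", {
  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(c(0, 1), each = 20)
  r <- association_test(x, y, "logistic")
  expect_false(r$converged)
})

test_that("per-allele tests on a bi-allelic STR are complementary", {
  set.seed(22)
  gt <- matrix(sample(c(0, 4), 200, TRUE), ncol = 2)
  y <- str_dosage(gt) + rnorm(100)
  res <- association_test(gt, y, "per_allele")
  expect_equal(nrow(res), 2)
  expect_equal(res$p_value[1], res$p_value[2], tolerance = 1e-10)
  expect_equal(res$beta_hat[1], -res$beta_hat[2], tolerance = 1e-10)
})

test_that("power is calibrated at beta = 0 and monotone in beta", {
  p <- make_panel(seed = 23, n_hap = 400, str_mut = 0.15)
  dos <- str_dosage(panel_str_genotypes(p))
  pw <- sapply(c(0, 0.1, 0.3), function(b)
    estimate_power(dos, list(causal = dos), beta = b, n_sims = 100,
                   seed = 50))
  expect_lte(pw[1], 0.12)
  expect_true(all(diff(pw) >= 0))
  expect_gt(pw[3], 0.9)
})

test_that("quantile normalisation maps ranks to normal scores", {
  expect_equal(quantile_normalize(c(5, 1, 9)),
               stats::qnorm(c(0.5, 1 / 6, 5 / 6)))
  set.seed(24)
  x <- rnorm(500)
  qx <- quantile_normalize(x)
  expect_equal(order(qx), order(x))
  expect_lt(abs(mean(qx)), 1e-10)
  # away from the extreme order statistics the scores track the sample
  inner <- 26:475
  expect_lt(max(abs(sort(qx)[inner] - sort(x)[inner])), 0.35)
})

test_that("eSTR scan finds a planted signal and respects covariates", {
  p <- make_panel(seed = 25, n_hap = 672, str_mut = 0.1)
  dos <- str_dosage(panel_str_genotypes(p))
  n <- length(dos)
  sex <- matrix(rep(c(-0.5, 0.5), length.out = n), ncol = 1,
                dimnames = list(NULL, "sex"))
  y <- simulate_expression(dos, beta = 0.5, covariates = sex,
                           gamma = 0.2, noise_sd = sqrt(0.75), seed = 9)
  expr <- matrix(y, nrow = 1, dimnames = list("gene1", NULL))
  dmat <- matrix(dos, nrow = 1, dimnames = list("str1", NULL))
  res <- estr_scan(expr, c(gene1 = 50000), dmat, c(str1 = 60000),
                   covariates = sex)
  expect_equal(res$flag, "ok")
  expect_lt(res$p_value, 1e-6)
  # an STR outside the 100 kb window is not tested
  res2 <- estr_scan(expr, c(gene1 = 50000), dmat, c(str1 = 200000),
                    covariates = sex)
  expect_equal(nrow(res2), 0)
  # a covariate fully explaining expression absorbs the signal
  y2 <- rnorm(n) + 5 * sex[, 1]
  expr2 <- matrix(y2, nrow = 1, dimnames = list("gene1", NULL))
  res3 <- estr_scan(expr2, c(gene1 = 50000), dmat, c(str1 = 60000),
                    covariates = sex)
  expect_gt(res3$p_value, 0.01)
  # genes with median expression 0 are excluded
  expr3 <- matrix(rep(0, n), nrow = 1, dimnames = list("gene0", NULL))
  expect_equal(nrow(estr_scan(expr3, c(gene0 = 50000), dmat,
                              c(str1 = 60000))), 0)
})

test_that("nested ANOVA isolates the STR's added signal", {
  p <- make_panel(seed = 26, n_hap = 672, str_mut = 0.1)
  estr <- str_dosage(panel_str_genotypes(p))
  snp <- panel_snp_dosages(p)
  tag <- best_tag_snp(estr, snp, p$sites$pos[p$sites$type == "snp"],
                      p$sites$pos[p$sites$type == "str"])
  esnp <- snp[, tag$id]
  # STR-generated expression: the STR adds signal beyond the SNP
  n_sig <- sum(sapply(1:20, function(i) {
    y <- simulate_expression(estr, beta = 0.5, noise_sd = sqrt(0.75),
                             seed = 100 + i)
    anova_nested_comparison(y, esnp, estr)$p_value < 0.05
  }))
  expect_gt(n_sig, 10)
  # identical predictors are flagged
  expect_equal(anova_nested_comparison(rnorm(336), esnp, esnp)$flag,
               "collinear")
})

test_that("per-allele tests beat the tag SNP under a quadratic trait", {
  p <- make_panel(seed = 27, n_hap = 500, str_mut = 0.2)
  gt <- panel_str_genotypes(p)
  dos <- str_dosage(gt)
  snp <- panel_snp_dosages(p)
  tag <- best_tag_snp(dos, snp, p$sites$pos[p$sites$type == "snp"],
                      p$sites$pos[p$sites$type == "str"])
  wins <- 0
  for (i in 1:50) {
    ph <- simulate_phenotype(gt, "quadratic", beta = 0.3, seed = 600 + i)
    pa <- association_test(gt, ph, "per_allele")
    p_best <- min(pa$p_value, na.rm = TRUE)
    p_snp <- association_test(snp[, tag$id], ph, "linear")$p_value
    wins <- wins + (p_best < p_snp)
  }
  expect_gt(wins, 25)
})
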