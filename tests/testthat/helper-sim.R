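# shared fixture builders (all generated in code, seeded)

# a small moderate-LD founder panel
make_panel <- function(seed = 1, n_hap = 120, n_snps = 40,
                       recomb = 0.002, str_mut = 0.08, ...) {
  simulate_founder_haplotypes(sim_config(
    n_founder_haplotypes = n_hap, n_snps = n_snps,
    recomb_switch_rate = recomb, str_mutation_rate = str_mut,
    seed = seed, ...))
}

# a perfect-LD panel: every haplotype is a copy of one of two seeds that
# carry distinct STR alleles
make_perfect_ld_panel <- function(seed = 1, n_hap = 60, n_snps = 30) {
  simulate_founder_haplotypes(sim_config(
    n_founder_haplotypes = n_hap, n_snps = n_snps,
    snp_mutation_rate = 0, recomb_switch_rate = 0, str_mutation_rate = 0,
    n_seed_haplotypes = 2, seed_str_alleles = c(0L, 3L), seed = seed))
}

# sever SNP-STR LD exactly by permuting STR alleles across haplotypes
permute_str_alleles <- function(panel, seed = 1) {
  set.seed(seed)
  sc <- which(panel$sites$type == "str")
  panel$H[, sc] <- sample(panel$H[, sc])
  panel
}

# observed/imputed genotype matrices from a leave-one-out table
loo_pairs <- function(loo) {
  list(truth = cbind(loo$obs_a, loo$obs_b),
       imputed = cbind(loo$imp_a, loo$imp_b))
}

# Monte-Carlo expected concordance under the random imputation model
mc_random_concordance <- function(freqs, n_draws = 1e5, seed = 1) {
  set.seed(seed)
  al <- seq_along(freqs)
  d <- function() matrix(sample(al, 2 * n_draws, TRUE, freqs), ncol = 2)
  g <- d(); h <- d()
  full <- (g[, 1] == h[, 1] & g[, 2] == h[, 2]) |
          (g[, 1] == h[, 2] & g[, 2] == h[, 1])
  any1 <- g[, 1] == h[, 1] | g[, 1] == h[, 2] |
          g[, 2] == h[, 1] | g[, 2] == h[, 2]
  sc <- ifelse(full, 1, ifelse(any1, 0.5, 0))
  c(mean = mean(sc), se = stats::sd(sc) / sqrt(n_draws))
}
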