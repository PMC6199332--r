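#' Simulation configuration for a synthetic SNP-STR region
#'
#' Parameters of the copy-with-mutation haplotype generator and of the
#' genotyping-error model. Haplotypes are generated sequentially: a small
#' number of independent seed haplotypes is drawn first, then each new
#' haplotype copies a previously generated one with per-site template
#' switching (tuning SNP-STR linkage disequilibrium directly), per-site SNP
#' mutation, and stepwise STR mutation. STR alleles are signed bp offsets
#' from the reference allele length; mutation steps act in repeat units and
#' are converted to bp with the motif period.
#'
#' @param n_founder_haplotypes number of haplotypes to generate (>= 2);
#'   two consecutive haplotypes form one founder sample.
#' @param n_snps number of SNP sites in the region (>= 1).
#' @param region_length region span in bp; SNP positions are drawn
#'   uniformly, the STR sits mid-region.
#' @param snp_mutation_rate per-site probability of flipping the copied
#'   SNP allele.
#' @param recomb_switch_rate per-site probability of switching the copy
#'   template to another previously generated haplotype.
#' @param str_mutation_rate per-copy probability of a stepwise STR
#'   mutation.
#' @param str_step_geom_p geometric parameter in (0, 1] for the mutation
#'   step size (k >= 1 repeat units, sign +/- with equal probability).
#' @param stutter_up,stutter_down per-called-allele probabilities of a +1
#'   resp. -1 repeat-unit PCR stutter shift.
#' @param dropout_rate per-call probability that a sample's STR genotype is
#'   set missing (both alleles).
#' @param motif STR motif string over A/C/G/T; `period = nchar(motif)`.
#' @param reference_length reference STR allele length in bp.
#' @param n_seed_haplotypes number of independent seed haplotypes (>= 1).
#' @param seed_str_alleles optional integer vector of repeat-unit offsets
#'   for the seed haplotypes' STR alleles (recycled); by default seeds take
#'   a short seeded stepwise walk from the reference.
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founder_haplotypes = 200L,
                       n_snps = 60L,
                       region_length = 100000L,
                       snp_mutation_rate = 0.002,
                       recomb_switch_rate = 0.002,
                       str_mutation_rate = 0.05,
                       str_step_geom_p = 0.7,
                       stutter_up = 0.01,
                       stutter_down = 0.02,
                       dropout_rate = 0.02,
                       motif = "AC",
                       reference_length = 20L,
                       n_seed_haplotypes = 2L,
                       seed_str_alleles = NULL,
                       seed = 1L) {
  cfg <- list(n_founder_haplotypes = as.integer(n_founder_haplotypes),
              n_snps = as.integer(n_snps),
              region_length = as.integer(region_length),
              snp_mutation_rate = snp_mutation_rate,
              recomb_switch_rate = recomb_switch_rate,
              str_mutation_rate = str_mutation_rate,
              str_step_geom_p = str_step_geom_p,
              stutter_up = stutter_up,
              stutter_down = stutter_down,
              dropout_rate = dropout_rate,
              motif = toupper(motif),
              reference_length = as.integer(reference_length),
              n_seed_haplotypes = as.integer(n_seed_haplotypes),
              seed_str_alleles = seed_str_alleles,
              seed = as.integer(seed))
  probs <- c("snp_mutation_rate", "recomb_switch_rate", "str_mutation_rate",
             "stutter_up", "stutter_down", "dropout_rate")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stop(p, " must be a probability in [0,1]")
  if (cfg$str_step_geom_p <= 0 || cfg$str_step_geom_p > 1)
    stop("str_step_geom_p must be in (0,1]")
  if (cfg$n_snps < 1L) stop("n_snps must be >= 1")
  if (cfg$n_founder_haplotypes < 2L)
    stop("n_founder_haplotypes must be >= 2")
  if (cfg$n_seed_haplotypes < 1L ||
      cfg$n_seed_haplotypes > cfg$n_founder_haplotypes)
    stop("n_seed_haplotypes must be in [1, n_founder_haplotypes]")
  if (!grepl("^[ACGT]+$", cfg$motif)) stop("motif must be over A,C,G,T")
  class(cfg) <- "sim_config"
  cfg
}

# signed stepwise mutation sizes, in repeat units: |k| >= 1 geometric
.str_steps <- function(n, geom_p) {
  if (n == 0L) return(integer(0))
  (stats::rgeom(n, geom_p) + 1L) * sample(c(-1L, 1L), n, replace = TRUE)
}

#' Simulate founder haplotypes with tunable SNP-STR LD
#'
#' Sequential copy-with-mutation generator: seed haplotypes get independent
#' Bernoulli(0.5) SNP alleles and a seeded stepwise-walk STR allele; every
#' later haplotype copies a uniformly chosen earlier haplotype with per-site
#' template switching, per-site SNP mutation, and a stepwise STR mutation.
#' Lower switching/mutation rates give stronger SNP-STR LD.
#'
#' @param config a [sim_config()].
#' @return A [hap_panel()] of `n_founder_haplotypes` phased haplotypes over
#'   `n_snps` SNPs plus one STR, two haplotypes per founder sample. When
#'   `n_founder_haplotypes` is odd the last haplotype is duplicated to
#'   complete the final sample.
#' @export
simulate_founder_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nh <- config$n_founder_haplotypes
  ns <- config$n_snps
  period <- nchar(config$motif)

  str_start <- as.integer(config$region_length %/% 2L)
  str_end <- str_start + config$reference_length - 1L
  snp_pos <- sort(sample(setdiff(seq_len(config$region_length),
                                 str_start:str_end), ns))
  sites <- data.frame(id = c(paste0("snp", seq_len(ns)), "str1"),
                      chrom = "chr1",
                      pos = c(snp_pos, str_start),
                      type = c(rep("snp", ns), "str"),
                      motif = c(rep(NA_character_, ns), config$motif),
                      period = c(rep(NA_integer_, ns), period),
                      reflen = c(rep(NA_integer_, ns),
                                 config$reference_length),
                      stringsAsFactors = FALSE)
  ord <- order(sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  nsite <- nrow(sites)
  str_col <- which(sites$type == "str")

  H <- matrix(0, nrow = nh, ncol = nsite)
  m <- config$n_seed_haplotypes
  for (h in seq_len(m)) {
    H[h, ] <- stats::rbinom(nsite, 1L, 0.5)
    if (is.null(config$seed_str_alleles)) {
      # seeds behave like copies of the reference allele: a stepwise
      # mutation event occurs with the same per-copy probability, so
      # str_mutation_rate = 0 leaves the locus monomorphic
      units <- if (h > 1L && stats::runif(1) < config$str_mutation_rate)
        .str_steps(1L, config$str_step_geom_p) else 0L
    } else {
      units <- config$seed_str_alleles[(h - 1L) %%
                                       length(config$seed_str_alleles) + 1L]
    }
    H[h, str_col] <- units * period
  }
  for (h in seq.int(m + 1L, length.out = nh - m)) {
    tmpl <- sample.int(h - 1L, 1L)
    hap <- numeric(nsite)
    sw <- stats::runif(nsite) < config$recomb_switch_rate
    for (s in seq_len(nsite)) {
      if (sw[s]) tmpl <- sample.int(h - 1L, 1L)
      hap[s] <- H[tmpl, s]
    }
    flip <- stats::runif(nsite) < config$snp_mutation_rate
    flip[str_col] <- FALSE
    hap[flip] <- 1 - hap[flip]
    if (stats::runif(1) < config$str_mutation_rate)
      hap[str_col] <- hap[str_col] +
        .str_steps(1L, config$str_step_geom_p) * period
    H[h, ] <- hap
  }
  if (nh %% 2L == 1L) H <- rbind(H, H[nh, , drop = FALSE])
  samples <- paste0("F", rep(seq_len(nrow(H) / 2L), each = 2L))
  hap_panel(sites, H, samples)
}

# diploid genotype container: unordered allele pairs per sample x site,
# plus the phased truth used by tests of the transmission phaser
new_str_genotypes <- function(sites, A1, A2, samples, phased) {
  rownames(A1) <- rownames(A2) <- samples
  colnames(A1) <- colnames(A2) <- sites$id
  structure(list(sites = sites, A1 = A1, A2 = A2, samples = samples,
                 phased = phased),
            class = "str_genotypes")
}

#' @export
print.str_genotypes <- function(x, ...) {
  cat("str_genotypes:", length(x$samples), "samples,",
      nrow(x$sites), "sites,", if (x$phased) "phased" else "unphased", "\n")
  invisible(x)
}

#' Extract the diploid STR genotype matrix from a genotype container
#'
#' @param genotypes a `str_genotypes` object.
#' @return n x 2 numeric matrix of STR allele bp offsets (unordered pairs),
#'   rownames = sample ids, `NA` for missing calls.
#' @export
str_genotype_matrix <- function(genotypes) {
  stopifnot(inherits(genotypes, "str_genotypes"))
  sc <- which(genotypes$sites$type == "str")
  out <- cbind(genotypes$A1[, sc], genotypes$A2[, sc])
  rownames(out) <- genotypes$samples
  colnames(out) <- c("allele_a", "allele_b")
  out
}

#' Extract the SNP dosage matrix from a genotype container
#'
#' @param genotypes a `str_genotypes` object.
#' @return n x m matrix of 0/1/2 counts of the `1` allele per SNP site.
#' @export
snp_dosage_matrix <- function(genotypes) {
  stopifnot(inherits(genotypes, "str_genotypes"))
  idx <- which(genotypes$sites$type == "snp")
  out <- genotypes$A1[, idx, drop = FALSE] +
         genotypes$A2[, idx, drop = FALSE]
  rownames(out) <- genotypes$samples
  out
}

# one meiosis: recombine a parent's two haplotypes by template switching
.meiose <- function(h1, h2, rate) {
  n <- length(h1)
  cur <- sample.int(2L, 1L)
  out <- numeric(n)
  sw <- stats::runif(n) < rate
  for (s in seq_len(n)) {
    if (sw[s]) cur <- 3L - cur
    out[s] <- if (cur == 1L) h1[s] else h2[s]
  }
  out
}

#' Simulate quad families from a founder haplotype panel
#'
#' Each parent draws two haplotypes with replacement from the panel; each
#' child receives one recombined haplotype from each parent (template
#' switching between the parent's two haplotypes at `recomb_switch_rate`
#' per site). Genotypes are emitted unphased (allele pairs sorted within
#' sample/site); the phased transmitted haplotypes are kept in the
#' `"truth"` attribute for validation.
#'
#' @param panel a [hap_panel()] with at least 4 haplotypes.
#' @param n_families number of quad families (>= 1).
#' @param seed integer RNG seed.
#' @param recomb_switch_rate per-site meiotic template-switch probability.
#' @return A list with `genotypes` (a `str_genotypes` over
#'   `4 * n_families` samples) and `quads` (data.frame with columns
#'   `family`, `father`, `mother`, `child1`, `child2`).
#' @export
simulate_quads <- function(panel, n_families, seed = 1L,
                           recomb_switch_rate = 0.001) {
  stopifnot(inherits(panel, "hap_panel"))
  if (nrow(panel$H) < 4L) stop("panel must have >= 4 haplotypes")
  if (n_families < 1L) stop("n_families must be >= 1")
  set.seed(as.integer(seed))
  nsite <- nrow(panel$sites)
  nsam <- 4L * n_families
  H1 <- matrix(NA_real_, nsam, nsite)  # paternal / first haplotype
  H2 <- matrix(NA_real_, nsam, nsite)
  samples <- character(nsam)
  quads <- data.frame(family = paste0("fam", seq_len(n_families)),
                      father = NA_character_, mother = NA_character_,
                      child1 = NA_character_, child2 = NA_character_,
                      stringsAsFactors = FALSE)
  for (f in seq_len(n_families)) {
    ids <- paste0("fam", f, "_", c("father", "mother", "child1", "child2"))
    quads[f, 2:5] <- ids
    rows <- (f - 1L) * 4L + 1:4
    samples[rows] <- ids
    fh <- panel$H[sample.int(nrow(panel$H), 2L, replace = TRUE), ,
                  drop = FALSE]
    mh <- panel$H[sample.int(nrow(panel$H), 2L, replace = TRUE), ,
                  drop = FALSE]
    H1[rows[1L], ] <- fh[1L, ]; H2[rows[1L], ] <- fh[2L, ]
    H1[rows[2L], ] <- mh[1L, ]; H2[rows[2L], ] <- mh[2L, ]
    for (k in 3:4) {
      H1[rows[k], ] <- .meiose(fh[1L, ], fh[2L, ], recomb_switch_rate)
      H2[rows[k], ] <- .meiose(mh[1L, ], mh[2L, ], recomb_switch_rate)
    }
  }
  A1 <- pmin(H1, H2)
  A2 <- pmax(H1, H2)
  geno <- new_str_genotypes(panel$sites, A1, A2, samples, phased = FALSE)
  rownames(H1) <- rownames(H2) <- samples
  attr(geno, "truth") <- list(H1 = H1, H2 = H2)
  list(genotypes = geno, quads = quads)
}

#' Inject PCR stutter and dropout into STR genotypes
#'
#' Independently per called STR allele, with probability `stutter_up`
#' (resp. `stutter_down`) the allele is shifted by +1 (resp. -1) repeat
#' unit; with probability `dropout_rate` the sample's STR genotype is set
#' missing (both alleles). SNP sites are untouched.
#'
#' @param genotypes a `str_genotypes` object.
#' @param config a [sim_config()] supplying the error rates and period.
#' @param seed integer RNG seed (defaults to `config$seed`).
#' @return The `str_genotypes` object with perturbed STR calls.
#' @export
inject_genotyping_errors <- function(genotypes, config, seed = config$seed) {
  stopifnot(inherits(genotypes, "str_genotypes"),
            inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  sc <- which(genotypes$sites$type == "str")
  period <- genotypes$sites$period[sc]
  n <- length(genotypes$samples)
  shift <- function(a) {
    u <- stats::runif(n)
    a + period * ((u < config$stutter_up) -
                  (u >= config$stutter_up &
                   u < config$stutter_up + config$stutter_down))
  }
  a1 <- shift(genotypes$A1[, sc])
  a2 <- shift(genotypes$A2[, sc])
  drop <- stats::runif(n) < config$dropout_rate
  a1[drop] <- NA_real_
  a2[drop] <- NA_real_
  genotypes$A1[, sc] <- pmin(a1, a2)
  genotypes$A2[, sc] <- pmax(a1, a2)
  genotypes
}

#' Simulate an expression vector from an STR dosage
#'
#' Generates `Y = beta * scaled(X) + C %*% gamma + eps` with
#' `eps ~ N(0, noise_sd^2)`: the generative counterpart of the eSTR
#' regression model.
#'
#' @param dosage numeric vector of STR dosages (finite).
#' @param beta effect size on the standardised dosage.
#' @param covariates optional numeric matrix (samples x k).
#' @param gamma covariate effects; defaults to ones.
#' @param noise_sd standard deviation of the error term.
#' @param seed integer RNG seed.
#' @return Numeric expression vector.
#' @export
simulate_expression <- function(dosage, beta, covariates = NULL,
                                gamma = NULL, noise_sd = 1, seed = 1L) {
  if (!all(is.finite(dosage))) stop("dosage vector must be finite")
  set.seed(as.integer(seed))
  n <- length(dosage)
  y <- beta * scale_genotype(dosage)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n)
      stop("covariates have ", nrow(covariates), " rows but ", n, " samples")
    if (is.null(gamma)) gamma <- rep(1, ncol(covariates))
    if (length(gamma) != ncol(covariates))
      stop("gamma length must match number of covariates")
    y <- y + as.numeric(covariates %*% gamma)
  }
  y + stats::rnorm(n, 0, noise_sd)
}
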