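#' Concordance score of two diploid STR genotypes
#'
#' Scores the imputed genotype against the true genotype as unordered
#' allele pairs under a one-to-one matching: 1 if both alleles match,
#' 0.5 if exactly one imputed allele can be matched to a true allele,
#' 0 if neither can. So (10,10) vs (10,12) scores 0.5, not 1.
#'
#' @param x,y length-2 numeric allele vectors (true, imputed); both must
#'   be non-missing.
#' @return 0, 0.5 or 1.
#' @export
genotype_concordance <- function(x, y) {
  if (anyNA(x) || anyNA(y)) stop("missing genotype")
  if (length(x) != 2 || length(y) != 2) stop("genotypes are allele pairs")
  pool <- y
  m <- 0L
  for (a in x) {
    hit <- match(a, pool)
    if (!is.na(hit)) {
      pool <- pool[-hit]
      m <- m + 1L
    }
  }
  c(0, 0.5, 1)[m + 1L]
}

# vectorised concordance over row-aligned n x 2 matrices
concordance_scores <- function(truth, imputed) {
  vapply(seq_len(nrow(truth)),
         function(i) genotype_concordance(truth[i, ], imputed[i, ]),
         numeric(1))
}

#' Exclude sample pairs carrying cohort-rare alleles
#'
#' Allele counts are taken from the observed genotypes of the whole
#' cohort; any sample whose observed or imputed genotype contains an
#' allele seen fewer than `min_count` times is excluded from concordance
#' metrics. An imputed allele never observed in the cohort has count 0 and
#' is therefore rare.
#'
#' @param truth,imputed row-aligned n x 2 allele matrices.
#' @param min_count minimum cohort allele count to retain (default 3).
#' @return Logical vector marking retained samples.
#' @export
filter_rare_alleles <- function(truth, imputed, min_count = 3) {
  called <- !is.na(truth[, 1]) & !is.na(truth[, 2])
  counts <- table(c(truth[called, 1], truth[called, 2]))
  cnt <- function(a) {
    out <- counts[as.character(a)]
    out[is.na(out)] <- 0
    as.numeric(out)
  }
  keep <- called & !is.na(imputed[, 1]) & !is.na(imputed[, 2])
  keep[keep] <- cnt(truth[keep, 1]) >= min_count &
                cnt(truth[keep, 2]) >= min_count &
                cnt(imputed[keep, 1]) >= min_count &
                cnt(imputed[keep, 2]) >= min_count
  keep
}

# unordered genotype table from allele frequencies under HWE:
# data.frame(a, b, prob) with a <= b
.hwe_genotype_table <- function(freqs) {
  al <- as.numeric(names(freqs))
  if (is.null(names(freqs))) al <- seq_along(freqs)
  n <- length(freqs)
  rows <- list()
  k <- 0L
  for (i in seq_len(n)) for (j in i:n) {
    k <- k + 1L
    rows[[k]] <- c(al[i], al[j],
                   if (i == j) freqs[i]^2 else 2 * freqs[i] * freqs[j])
  }
  m <- do.call(rbind, rows)
  data.frame(a = m[, 1], b = m[, 2], prob = m[, 3])
}

#' Expected concordance under the random imputation model
#'
#' The random model imputes genotypes by drawing two alleles independently
#' from the cohort allele frequencies. The expectation is computed exactly
#' by summing concordance over all genotype pairs weighted by their HWE
#' probabilities.
#'
#' @param allele_freqs named (by allele length) or unnamed frequency
#'   vector summing to 1.
#' @return Expected concordance in \[0, 1\].
#' @export
random_model_concordance <- function(allele_freqs) {
  if (length(allele_freqs) == 0) stop("empty frequency vector")
  if (abs(sum(allele_freqs) - 1) > 1e-9)
    stop("frequencies must sum to 1")
  if (length(allele_freqs) == 1) return(1)
  gt <- .hwe_genotype_table(allele_freqs)
  tot <- 0
  for (g in seq_len(nrow(gt))) for (h in seq_len(nrow(gt))) {
    tot <- tot + gt$prob[g] * gt$prob[h] *
      genotype_concordance(c(gt$a[g], gt$b[g]), c(gt$a[h], gt$b[h]))
  }
  tot
}

# modal unordered diploid genotype; ties -> smaller dosage, then
# lexicographic on (a, b)
.modal_genotype <- function(obs) {
  key <- paste(obs[, 1], obs[, 2], sep = "/")
  tab <- table(key)
  cand <- names(tab)[tab == max(tab)]
  mat <- do.call(rbind, lapply(strsplit(cand, "/"), as.numeric))
  ord <- order(mat[, 1] + mat[, 2], mat[, 1], mat[, 2])
  mat[ord[1], ]
}

#' Expected concordance under the naive imputation model
#'
#' The naive model always imputes the cohort's most frequent diploid
#' genotype (empirical genotype counts; ties resolved to the genotype
#' with the smaller dosage, then lexicographically). Returns the mean
#' concordance of every observed genotype against that modal genotype.
#'
#' @param obs n x 2 matrix of observed allele pairs (non-missing rows are
#'   used).
#' @return Expected concordance in \[0, 1\].
#' @export
naive_model_concordance <- function(obs) {
  obs <- obs[!is.na(obs[, 1]) & !is.na(obs[, 2]), , drop = FALSE]
  if (nrow(obs) == 0) stop("need at least one observed genotype")
  modal <- .modal_genotype(obs)
  mean(vapply(seq_len(nrow(obs)),
              function(i) genotype_concordance(obs[i, ], modal),
              numeric(1)))
}

#' Length and allelic r2 under the random imputation model
#'
#' Draws one random diploid genotype per sample (two independent allele
#' draws from the observed allele frequencies, fixed seed) and evaluates
#' the r2 metrics against the observed genotypes.
#'
#' @param obs n x 2 matrix of observed allele pairs.
#' @param seed integer RNG seed.
#' @param common_freq frequency threshold for the allelic r2 map
#'   (default 0.05).
#' @return list with `length_r2` and `allelic_r2` (named vector over
#'   common alleles); metrics are `NA` where a draw has zero variance.
#' @export
random_model_r2 <- function(obs, seed = 1L, common_freq = 0.05) {
  called <- !is.na(obs[, 1]) & !is.na(obs[, 2])
  obs <- obs[called, , drop = FALSE]
  if (nrow(obs) < 2) stop("need >= 2 samples")
  set.seed(as.integer(seed))
  alleles <- c(obs[, 1], obs[, 2])
  tab <- table(alleles)
  freqs <- as.numeric(tab) / sum(tab)
  vals <- as.numeric(names(tab))
  n <- nrow(obs)
  drawn <- if (length(vals) == 1) rep(vals, 2L * n) else
    sample(vals, 2L * n, replace = TRUE, prob = freqs)
  draw <- matrix(drawn, n, 2L)
  lr2 <- if (length(vals) < 2) NA_real_ else
    tryCatch(length_r2(str_dosage(obs), str_dosage(draw)),
             error = function(e) NA_real_)
  common <- vals[freqs >= common_freq]
  ar2 <- vapply(common, function(a) allelic_r2(obs, draw, a), numeric(1))
  names(ar2) <- common
  list(length_r2 = lr2, allelic_r2 = ar2)
}

#' Per-locus evaluation of imputed against observed STR genotypes
#'
#' Applies the cohort rare-allele exclusion, then assembles observed
#' concordance, length r2 and per-common-allele allelic r2, together with
#' the naive and random null expectations. A locus is flagged
#' multi-allelic when it has three or more common alleles.
#'
#' @param truth,imputed row-aligned n x 2 allele matrices (observed,
#'   imputed).
#' @param seed RNG seed for the random-model r2 draws.
#' @param common_freq common-allele frequency threshold (default 0.05).
#' @param min_count rare-allele cohort count threshold (default 3).
#' @return list of class `locus_eval` with fields `n_samples`,
#'   `concordance`, `length_r2`, `allelic_r2` (named vector),
#'   `naive_concordance`, `random_concordance`, `random_length_r2`,
#'   `random_allelic_r2`, `multi_allelic`. Metrics are `NA` when fewer
#'   than 2 evaluable pairs remain.
#' @export
evaluate_locus <- function(truth, imputed, seed = 1L, common_freq = 0.05,
                           min_count = 3) {
  stopifnot(nrow(truth) == nrow(imputed))
  keep <- filter_rare_alleles(truth, imputed, min_count)
  out <- list(n_samples = sum(keep), concordance = NA_real_,
              length_r2 = NA_real_, allelic_r2 = numeric(0),
              naive_concordance = NA_real_, random_concordance = NA_real_,
              random_length_r2 = NA_real_, random_allelic_r2 = numeric(0),
              multi_allelic = NA)
  class(out) <- "locus_eval"
  if (sum(keep) < 2) return(out)
  tr <- truth[keep, , drop = FALSE]
  im <- imputed[keep, , drop = FALSE]
  tab <- table(c(tr[, 1], tr[, 2]))
  freqs <- as.numeric(tab) / sum(tab)
  names(freqs) <- names(tab)
  common <- as.numeric(names(freqs))[freqs >= common_freq]

  out$n_samples <- nrow(tr)
  out$concordance <- mean(concordance_scores(tr, im))
  out$length_r2 <- if (length(freqs) < 2) NA_real_ else
    tryCatch(length_r2(str_dosage(tr), str_dosage(im)),
             error = function(e) NA_real_)
  ar2 <- vapply(common, function(a) allelic_r2(tr, im, a), numeric(1))
  names(ar2) <- common
  out$allelic_r2 <- ar2
  out$naive_concordance <- naive_model_concordance(tr)
  out$random_concordance <- random_model_concordance(freqs)
  rnd <- random_model_r2(tr, seed = seed, common_freq = common_freq)
  out$random_length_r2 <- rnd$length_r2
  out$random_allelic_r2 <- rnd$allelic_r2
  out$multi_allelic <- length(common) >= 3
  out
}

#' @export
print.locus_eval <- function(x, ...) {
  cat(sprintf(paste0("locus_eval: n=%d  C=%.3f (naive %.3f, random %.3f)",
                     "  length r2=%.3f\n"),
              x$n_samples, x$concordance, x$naive_concordance,
              x$random_concordance, x$length_r2))
  invisible(x)
}

#' Summarise per-locus evaluation reports
#'
#' Means across loci of the observed, naive and random concordance and of
#' the observed/random length and allelic r2 (per-locus allelic r2 first
#' averaged over common alleles), reported for all loci and for the
#' multi-allelic stratum (>= 3 common alleles).
#'
#' @param reports list of `locus_eval` objects.
#' @return data.frame with rows `all` and `multi_allelic`.
#' @export
summarize_evaluation <- function(reports) {
  one <- function(rs) {
    g <- function(f) mean(vapply(rs, f, numeric(1)), na.rm = TRUE)
    data.frame(
      n_loci = length(rs),
      concordance = g(function(r) r$concordance),
      naive_concordance = g(function(r) r$naive_concordance),
      random_concordance = g(function(r) r$random_concordance),
      length_r2 = g(function(r) r$length_r2),
      random_length_r2 = g(function(r) r$random_length_r2),
      allelic_r2 = g(function(r) if (length(r$allelic_r2))
        mean(r$allelic_r2, na.rm = TRUE) else NA_real_),
      random_allelic_r2 = g(function(r) if (length(r$random_allelic_r2))
        mean(r$random_allelic_r2, na.rm = TRUE) else NA_real_))
  }
  multi <- Filter(function(r) isTRUE(r$multi_allelic), reports)
  out <- rbind(one(reports),
               if (length(multi)) one(multi) else one(reports)[0, ])
  rownames(out) <- c("all", if (length(multi)) "multi_allelic")
  out
}
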