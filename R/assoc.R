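#' Standardise a genotype dosage vector
#'
#' Centres to mean 0 and scales to population variance 1 (divisor n, not
#' n - 1), the convention used throughout the trait simulations.
#'
#' @param x numeric vector with at least 2 distinct values.
#' @return Scaled numeric vector.
#' @export
scale_genotype <- function(x) {
  if (length(unique(x[!is.na(x)])) < 2)
    stop("cannot scale a constant genotype vector")
  xc <- x - mean(x)
  xc / sqrt(mean(xc^2))
}

#' Simulate a phenotype from STR genotypes
#'
#' Three generating models on the standardised genotype `G`:
#' `additive`: `P = beta * G + E`, `E ~ N(0, 1 - beta)` (variance,
#' requiring `beta <= 1`); `case_control`: Bernoulli outcome with
#' `logit(p_i) = beta * G_i`; `quadratic`: `P = beta * Gq + E` where `Gq`
#' is the squared dosage divided by the cohort mean absolute allele
#' length, then standardised.
#'
#' @param genotypes n x 2 matrix of allele bp offsets (required for the
#'   quadratic model), or a numeric dosage vector.
#' @param model one of `"additive"`, `"case_control"`, `"quadratic"`.
#' @param beta effect size.
#' @param seed integer RNG seed.
#' @param reference_length reference allele length in bp, used to form
#'   absolute allele lengths for the quadratic model's divisor.
#' @return list of class `phenotype_set` with `values`, `model`, `beta`,
#'   `seed`.
#' @export
simulate_phenotype <- function(genotypes, model = c("additive",
                               "case_control", "quadratic"),
                               beta = 0.1, seed = 1L,
                               reference_length = 20) {
  model <- match.arg(model)
  set.seed(as.integer(seed))
  if (is.matrix(genotypes)) {
    dos <- str_dosage(genotypes)
  } else dos <- genotypes
  n <- length(dos)
  if (model == "quadratic") {
    if (!is.matrix(genotypes))
      stop("quadratic model needs the n x 2 allele matrix")
    mean_len <- mean(genotypes + reference_length)
    g <- scale_genotype(str_dosage(genotypes)^2 / mean_len)
  } else g <- scale_genotype(dos)
  values <- switch(model,
    additive = ,
    quadratic = {
      if (beta > 1) stop("additive/quadratic beta > 1 gives negative ",
                         "noise variance (1 - beta)")
      g * beta + stats::rnorm(n, 0, sqrt(1 - beta))
    },
    case_control = stats::rbinom(n, 1L, stats::plogis(beta * g)))
  structure(list(values = values, model = model, beta = beta,
                 seed = as.integer(seed)),
            class = "phenotype_set")
}

.phen_values <- function(phenotype) {
  if (inherits(phenotype, "phenotype_set")) phenotype$values else phenotype
}

#' Association test between a genotype encoding and a phenotype
#'
#' `linear` fits ordinary least squares of the phenotype on the dosage and
#' tests the slope; `logistic` fits a maximum-likelihood logit model;
#' `per_allele` runs one linear (or logistic, for 0/1 phenotypes) test per
#' distinct allele on its 0/1/2 copy-count encoding.
#'
#' @param genotype numeric dosage vector, or for `per_allele` an n x 2
#'   allele matrix.
#' @param phenotype numeric vector or `phenotype_set`.
#' @param kind `"linear"`, `"logistic"` or `"per_allele"`.
#' @param variant optional variant id carried into the result.
#' @return For `linear`/`logistic`: list with `beta_hat`, `se`, `p_value`,
#'   `kind`, `variant`, `converged`. For `per_allele`: data.frame with one
#'   row per allele.
#' @export
association_test <- function(genotype, phenotype,
                             kind = c("linear", "logistic", "per_allele"),
                             variant = NA_character_) {
  kind <- match.arg(kind)
  y <- .phen_values(phenotype)
  if (kind == "per_allele") {
    if (!is.matrix(genotype))
      stop("per_allele testing needs the n x 2 allele matrix")
    alleles <- sort(unique(c(genotype[, 1], genotype[, 2])))
    sub <- if (all(y %in% c(0, 1))) "logistic" else "linear"
    rows <- lapply(alleles, function(a) {
      cc <- .allele_counts(genotype, a)
      r <- if (length(unique(cc)) < 2)
        list(beta_hat = NA_real_, se = NA_real_, p_value = NA_real_,
             converged = FALSE)
      else association_test(cc, y, sub, variant = as.character(a))
      data.frame(allele = a, beta_hat = r$beta_hat, se = r$se,
                 p_value = r$p_value, converged = r$converged)
    })
    return(do.call(rbind, rows))
  }
  if (length(y) < 10) stop("need n >= 10 samples")
  if (length(unique(genotype)) < 2)
    stop("genotype encoding is constant")
  if (kind == "linear") {
    fit <- stats::lm(y ~ genotype)
    cf <- summary(fit)$coefficients
    return(list(beta_hat = cf[2, 1], se = cf[2, 2], p_value = cf[2, 4],
                kind = kind, variant = variant, converged = TRUE))
  }
  fit <- suppressWarnings(stats::glm(y ~ genotype,
                                     family = stats::binomial()))
  cf <- summary(fit)$coefficients
  conv <- fit$converged && abs(cf[2, 1]) < 15 && cf[2, 2] < 100
  list(beta_hat = cf[2, 1], se = cf[2, 2], p_value = cf[2, 4],
       kind = kind, variant = variant, converged = conv)
}

#' Power estimation by repeated trait simulation
#'
#' Simulates phenotypes from the causal STR under the chosen model and
#' records, for each supplied genotype encoding (e.g. causal STR dosage,
#' imputed STR dosage, best tag SNP dosage), the fraction of simulations
#' with nominal association p-value below `alpha`.
#'
#' @param causal n x 2 allele matrix (or dosage vector for non-quadratic
#'   models) generating the phenotype.
#' @param encodings named list of numeric dosage vectors to test.
#' @param model generating model, see [simulate_phenotype()].
#' @param beta effect size (default 0.1).
#' @param n_sims number of simulations (default 100).
#' @param alpha significance level (default 0.05).
#' @param seed base RNG seed; simulation i uses `seed + i`.
#' @param reference_length passed to [simulate_phenotype()].
#' @return Named numeric vector of power estimates, one per encoding.
#' @export
estimate_power <- function(causal, encodings, model = "additive",
                           beta = 0.1, n_sims = 100, alpha = 0.05,
                           seed = 1L, reference_length = 20) {
  if (n_sims < 1) stop("n_sims must be >= 1")
  kind <- if (model == "case_control") "logistic" else "linear"
  hits <- numeric(length(encodings))
  names(hits) <- names(encodings)
  for (i in seq_len(n_sims)) {
    ph <- simulate_phenotype(causal, model, beta, seed = seed + i,
                             reference_length = reference_length)
    for (k in seq_along(encodings)) {
      r <- association_test(encodings[[k]], ph, kind)
      hits[k] <- hits[k] + (r$p_value < alpha)
    }
  }
  hits / n_sims
}

#' Quantile normalisation to a standard normal
#'
#' Rank-based mapping of values to standard-normal quantiles with the
#' (r - 0.5)/n plotting position; ties share the average rank.
#'
#' @param values numeric vector with at least 2 values.
#' @return Numeric vector of normal scores (rank-preserving).
#' @export
quantile_normalize <- function(values) {
  n <- length(values)
  if (n < 2) stop("need >= 2 values")
  stats::qnorm((rank(values, ties.method = "average") - 0.5) / n)
}

#' Expression-STR (eSTR) association scan
#'
#' For each gene within `window_bp` of an STR: genes with median
#' expression 0 are dropped, expression is quantile-normalised to a
#' standard normal, the STR dosage is standardised, and a linear model
#' with covariates is fit; the dosage slope and p-value are reported.
#' Gene x STR pairs with collinear covariates are flagged and skipped.
#'
#' @param expression genes x samples numeric matrix (rownames = gene ids).
#' @param gene_pos named numeric vector of gene positions (bp).
#' @param str_dosages STRs x samples numeric matrix (rownames = STR ids).
#' @param str_pos named numeric vector of STR positions (bp).
#' @param covariates optional samples x k numeric matrix.
#' @param window_bp cis window around the gene (default 100 kb).
#' @return data.frame with columns `gene`, `str`, `beta_hat`, `se`,
#'   `p_value`, `flag`.
#' @export
estr_scan <- function(expression, gene_pos, str_dosages, str_pos,
                      covariates = NULL, window_bp = 1e5) {
  stopifnot(is.matrix(expression), is.matrix(str_dosages))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != ncol(expression))
      stop("covariate rows must align with expression samples")
  }
  rows <- list()
  for (g in rownames(expression)) {
    ev <- expression[g, ]
    if (stats::median(ev) == 0) next
    y <- quantile_normalize(ev)
    near <- rownames(str_dosages)[abs(str_pos[rownames(str_dosages)] -
                                      gene_pos[g]) <= window_bp]
    for (s in near) {
      x <- tryCatch(scale_genotype(str_dosages[s, ]),
                    error = function(e) NULL)
      if (is.null(x)) next
      df <- if (is.null(covariates)) data.frame(y = y, x = x)
            else data.frame(y = y, x = x, covariates)
      fit <- stats::lm(y ~ ., data = df)
      cf <- summary(fit)$coefficients
      if (anyNA(fit$coefficients) || !"x" %in% rownames(cf)) {
        rows[[length(rows) + 1L]] <-
          data.frame(gene = g, str = s, beta_hat = NA_real_, se = NA_real_,
                     p_value = NA_real_, flag = "collinear")
        next
      }
      rows[[length(rows) + 1L]] <-
        data.frame(gene = g, str = s, beta_hat = cf["x", 1],
                   se = cf["x", 2], p_value = cf["x", 4], flag = "ok")
    }
  }
  if (length(rows) == 0)
    return(data.frame(gene = character(), str = character(),
                      beta_hat = numeric(), se = numeric(),
                      p_value = numeric(), flag = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nested-model ANOVA: does the eSTR add signal beyond the best eSNP?
#'
#' Compares `Y ~ eSNP` against `Y ~ eSNP + eSTR` with an F-test on the
#' one extra parameter.
#'
#' @param y expression vector (n > 3).
#' @param esnp,estr dosage vectors for the lead eSNP and the eSTR.
#' @return list with `p_value` (`NA` when the eSTR is collinear with the
#'   eSNP) and `flag`.
#' @export
anova_nested_comparison <- function(y, esnp, estr) {
  if (length(y) <= 3) stop("need n > 3")
  resid_var <- stats::var(stats::residuals(stats::lm(estr ~ esnp)))
  if (is.na(resid_var) || resid_var < 1e-12)
    return(list(p_value = NA_real_, flag = "collinear"))
  fit0 <- stats::lm(y ~ esnp)
  fit1 <- stats::lm(y ~ esnp + estr)
  p <- stats::anova(fit0, fit1)[2, "Pr(>F)"]
  list(p_value = p, flag = "ok")
}
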