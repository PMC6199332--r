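#' STR genotype dosage
#'
#' The dosage of a diploid STR genotype is the sum of its two allele
#' lengths (bp offsets from the reference allele).
#'
#' @param gt n x 2 numeric allele matrix, or a length-2 vector for a
#'   single genotype.
#' @return Numeric dosage vector (`NA` where either allele is missing).
#' @export
str_dosage <- function(gt) {
  if (is.null(dim(gt))) {
    if (length(gt) != 2) stop("a genotype is a pair of alleles")
    return(sum(gt))
  }
  rowSums(gt)
}

#' Squared Pearson correlation between two dosage vectors (length r2)
#'
#' Pairwise-complete deletion is applied first. Undefined (NA, not 0)
#' when fewer than two complete pairs remain or either vector has zero
#' variance.
#'
#' @param x,y numeric dosage vectors of equal length.
#' @return r^2 in \[0, 1\], or `NA`.
#' @export
length_r2 <- function(x, y) {
  if (length(x) != length(y)) stop("dosage vectors must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) stop("need >= 2 paired non-missing values")
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

# per-sample copy counts (0/1/2) of one allele length
.allele_counts <- function(gt, allele) {
  (gt[, 1] == allele) + (gt[, 2] == allele)
}

#' Per-allele r2 between true and imputed genotypes (allelic r2)
#'
#' Treats one STR allele as a bi-allelic locus: per sample, the number of
#' copies (0/1/2) of `allele` is counted in the true and in the imputed
#' genotype, and the squared Pearson correlation of the two count vectors
#' is returned.
#'
#' @param truth,imputed n x 2 allele matrices (row-aligned samples).
#' @param allele allele length (bp offset) observed in the truth set.
#' @return r^2, or `NA` if either count vector has zero variance.
#' @export
allelic_r2 <- function(truth, imputed, allele) {
  if (!allele %in% c(truth[, 1], truth[, 2]))
    stop("allele ", allele, " not observed in the truth set")
  xa <- .allele_counts(truth, allele)
  ya <- .allele_counts(imputed, allele)
  ok <- !is.na(xa) & !is.na(ya)
  xa <- xa[ok]; ya <- ya[ok]
  if (length(xa) < 2 || stats::var(xa) == 0 || stats::var(ya) == 0)
    return(NA_real_)
  stats::cor(xa, ya)^2
}

#' Best tag SNP for an STR
#'
#' Among SNPs within `window_kb` of the STR start, returns the SNP whose
#' minor-allele dosage has the highest length r2 with the STR dosage.
#' Ties are broken by smaller distance to the STR, then lower genomic
#' position. Distance = |SNP pos - STR start|.
#'
#' @param str_dosages numeric STR dosage vector over samples.
#' @param snp_dosages samples x SNPs matrix of 0/1/2 allele counts.
#' @param snp_pos SNP positions (bp), parallel to `snp_dosages` columns.
#' @param str_start STR start coordinate (bp).
#' @param window_kb window half-width in kb (default 50).
#' @return list with `id`, `distance` (bp), `length_r2`; or `NULL` with a
#'   message when no SNP lies in the window.
#' @export
best_tag_snp <- function(str_dosages, snp_dosages, snp_pos, str_start,
                         window_kb = 50) {
  stopifnot(ncol(snp_dosages) == length(snp_pos))
  dist <- abs(snp_pos - str_start)
  in_win <- dist <= window_kb * 1000
  if (!any(in_win)) {
    message("no tag SNP: empty window around position ", str_start)
    return(NULL)
  }
  idx <- which(in_win)
  r2 <- vapply(idx, function(j) {
    d <- snp_dosages[, j]
    if (mean(d, na.rm = TRUE) > 1) d <- 2 - d  # minor-allele coding
    tryCatch(length_r2(str_dosages, d), error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(r2))) {
    message("no tag SNP: all candidate r2 undefined")
    return(NULL)
  }
  ord <- order(-r2, dist[idx], snp_pos[idx], na.last = TRUE)
  j <- idx[ord[1]]
  ids <- colnames(snp_dosages)
  list(id = if (is.null(ids)) j else ids[j],
       distance = dist[j],
       length_r2 = r2[ord[1]])
}
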