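#' Haplotype panel constructor
#'
#' A haplotype panel holds fully phased haplotypes over one genomic region:
#' an ordered site list (SNPs plus a single STR), an allele matrix with one
#' row per haplotype, and a haplotype-to-sample map (two haplotypes per
#' sample). SNP alleles are coded 0/1; the STR allele is a signed base-pair
#' offset from the declared reference length.
#'
#' @param sites data.frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   `type` (`"snp"` or `"str"`), and for the STR row `motif`, `period`
#'   (bp, 1-6) and `reflen` (reference allele length in bp).
#' @param H numeric matrix, haplotypes x sites; no missing values allowed.
#' @param samples character vector mapping each row of `H` to a sample id;
#'   each sample must appear exactly twice.
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(sites, H, samples) {
  stopifnot(is.data.frame(sites), is.matrix(H))
  req <- c("id", "chrom", "pos", "type")
  if (!all(req %in% names(sites)))
    stop("sites must have columns: ", paste(req, collapse = ", "))
  if (ncol(H) != nrow(sites))
    stop("allele matrix has ", ncol(H), " columns but ", nrow(sites), " sites")
  if (length(samples) != nrow(H))
    stop("sample map length must equal number of haplotypes")
  if (anyNA(H))
    stop("panel haplotypes must be fully resolved (no missing alleles)")
  tab <- table(samples)
  if (any(tab != 2L))
    stop("every sample must contribute exactly two haplotypes")
  if (sum(sites$type == "str") != 1L)
    stop("a panel region must contain exactly one STR site")
  colnames(H) <- sites$id
  structure(list(sites = sites, H = H, samples = samples),
            class = "hap_panel")
}

#' @export
print.hap_panel <- function(x, ...) {
  cat("hap_panel:", nrow(x$H), "haplotypes (",
      length(unique(x$samples)), "samples ),",
      sum(x$sites$type == "snp"), "SNPs + 1 STR\n")
  invisible(x)
}

# index of the single STR site
str_site_index <- function(panel) which(panel$sites$type == "str")

snp_site_index <- function(panel) which(panel$sites$type == "snp")

#' STR alleles carried by each haplotype of a panel
#'
#' @param panel a `hap_panel`.
#' @return numeric vector of bp offsets, one per haplotype.
#' @export
panel_str_alleles <- function(panel) {
  unname(panel$H[, str_site_index(panel)])
}

#' Diploid STR genotypes of the samples in a panel
#'
#' @param panel a `hap_panel`.
#' @return n x 2 numeric matrix of bp offsets (unordered pairs, sorted
#'   within row), rownames = sample ids.
#' @export
panel_str_genotypes <- function(panel) {
  a <- panel_str_alleles(panel)
  ids <- unique(panel$samples)
  out <- t(vapply(ids, function(s) sort(a[panel$samples == s]),
                  numeric(2)))
  rownames(out) <- ids
  out
}

#' Diploid SNP dosages of the samples in a panel
#'
#' @param panel a `hap_panel`.
#' @return n x m matrix of 0/1/2 counts of the `1` allele, one column per
#'   SNP site, rownames = sample ids.
#' @export
panel_snp_dosages <- function(panel) {
  idx <- snp_site_index(panel)
  ids <- unique(panel$samples)
  out <- t(vapply(ids, function(s) colSums(panel$H[panel$samples == s, idx,
                                                   drop = FALSE]),
                  numeric(length(idx))))
  rownames(out) <- ids
  colnames(out) <- panel$sites$id[idx]
  out
}

#' Remove one sample's haplotypes from a panel
#'
#' @param panel a `hap_panel`.
#' @param sample sample id to drop.
#' @return A reduced `hap_panel`.
#' @export
drop_sample <- function(panel, sample) {
  keep <- panel$samples != sample
  if (all(keep)) stop("sample not in panel: ", sample)
  hap_panel(panel$sites, panel$H[keep, , drop = FALSE], panel$samples[keep])
}
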