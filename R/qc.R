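#' Expected STR heterozygosity
#'
#' H = 1 - sum(p_i^2) over length-allele frequencies: the probability that
#' two randomly drawn alleles differ. Alleles of identical length are
#' collapsed into a single frequency class before the sum when `lengths`
#' is supplied.
#'
#' @param allele_freqs nonnegative frequencies summing to 1 (within 1e-9).
#' @param lengths optional allele lengths parallel to `allele_freqs`;
#'   frequencies sharing a length are summed first.
#' @return H in \[0, 1\].
#' @export
expected_heterozygosity <- function(allele_freqs, lengths = NULL) {
  if (length(allele_freqs) == 0) stop("empty frequency vector")
  if (any(allele_freqs < 0)) stop("frequencies must be nonnegative")
  if (abs(sum(allele_freqs) - 1) > 1e-9)
    stop("frequencies must sum to 1 (got ", sum(allele_freqs), ")")
  if (!is.null(lengths)) {
    cl <- collapse_length_alleles(lengths, allele_freqs)
    allele_freqs <- cl$freq
  }
  1 - sum(allele_freqs^2)
}

#' Collapse sequence-level alleles into length alleles
#'
#' STR alleles that differ in sequence but share a length are treated as
#' one allele; their frequencies are summed within each length class.
#'
#' @param lengths numeric allele lengths (one per sequence-level allele).
#' @param freqs frequencies parallel to `lengths`.
#' @return data.frame with one row per distinct length, columns `length`
#'   and `freq`, sorted by length.
#' @export
collapse_length_alleles <- function(lengths, freqs) {
  if (length(lengths) != length(freqs))
    stop("lengths and freqs must have equal length")
  agg <- tapply(freqs, lengths, sum)
  data.frame(length = as.numeric(names(agg)), freq = as.numeric(agg),
             row.names = NULL)
}

#' Exact binomial Hardy-Weinberg test on the heterozygote count
#'
#' Under HWE the probability that a call is heterozygous equals the
#' expected heterozygosity H of the allele frequencies. The observed
#' heterozygote count among `n_het + n_hom` calls is tested against
#' Binomial(n, H) with an exact two-sided p-value (minimum-likelihood
#' method, as in [stats::binom.test()]). Chosen over a genotype-table
#' chi-square because it stays well-defined for many-allele STRs.
#'
#' @param n_het,n_hom heterozygous / homozygous call counts
#'   (`n_het + n_hom >= 1`).
#' @param allele_freqs allele frequencies (length-collapsed).
#' @return Two-sided p-value; 1 for a monomorphic locus.
#' @export
hwe_het_test <- function(n_het, n_hom, allele_freqs) {
  n <- n_het + n_hom
  if (n < 1) stop("need at least one call")
  h <- expected_heterozygosity(allele_freqs)
  if (h <= 0 || h >= 1) return(1)
  d <- stats::dbinom(0:n, n, h)
  p <- sum(d[d <= d[n_het + 1L] * (1 + 1e-7)])
  min(1, p)
}

#' Mendelian inheritance rate at one STR
#'
#' A child call is consistent if one of its alleles can be drawn from the
#' father's pair and the other from the mother's pair. Families in which
#' all four members are homozygous for the reference allele (offset 0) are
#' excluded; only families with complete genotypes for all four members
#' are counted.
#'
#' @param quads data.frame with columns `father`, `mother`, `child1`,
#'   `child2` (sample ids).
#' @param gt n x 2 numeric matrix of STR allele offsets with sample ids as
#'   rownames; `NA` marks missing calls.
#' @return Fraction of consistent child calls, or `NA` if no child call is
#'   countable.
#' @export
mendelian_rate <- function(quads, gt) {
  members <- unlist(quads[, c("father", "mother", "child1", "child2")])
  missing_ids <- setdiff(members, rownames(gt))
  if (length(missing_ids) > 0)
    stop("unknown sample in pedigree: ", paste(missing_ids, collapse = ", "))
  n_cons <- 0L
  n_tot <- 0L
  for (f in seq_len(nrow(quads))) {
    fa <- gt[quads$father[f], ]
    mo <- gt[quads$mother[f], ]
    kids <- rbind(gt[quads$child1[f], ], gt[quads$child2[f], ])
    if (anyNA(fa) || anyNA(mo) || anyNA(kids)) next
    if (all(c(fa, mo, kids) == 0)) next  # hom-ref in all members
    for (k in 1:2) {
      ok <- (kids[k, 1] %in% fa && kids[k, 2] %in% mo) ||
            (kids[k, 2] %in% fa && kids[k, 1] %in% mo)
      n_cons <- n_cons + ok
      n_tot <- n_tot + 1L
    }
  }
  if (n_tot == 0L) return(NA_real_)
  n_cons / n_tot
}

# longest single-base run in a sequence string
.max_homopolymer_run <- function(seq) {
  if (is.na(seq) || nchar(seq) == 0) return(0L)
  max(rle(strsplit(toupper(seq), "")[[1]])$lengths)
}

#' Read a BED file of exclusion regions
#'
#' Three-column BED, 0-based half-open. Malformed lines raise an error
#' naming the line number.
#'
#' @param path path to a BED file.
#' @return data.frame with columns `chrom`, `start0`, `end0`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t| +")[[1]]
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (length(f) < 3 || is.na(s) || is.na(e) || e < s)
      stop("malformed BED line ", i, ": ", lines[i])
    out[[i]] <- data.frame(chrom = f[1], start0 = s, end0 = e,
                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start0 = numeric(),
                      end0 = numeric()))
  do.call(rbind, out)
}

# does a 1-based inclusive interval overlap any BED interval by >= 1 bp?
.overlaps_bed <- function(chrom, start, end, bed) {
  if (is.null(bed) || nrow(bed) == 0) return(FALSE)
  s0 <- start - 1  # to 0-based half-open
  e0 <- end
  any(bed$chrom == chrom & s0 < bed$end0 & bed$start0 < e0)
}

#' Locus-level STR quality-control filters
#'
#' Applies five locus filters: overlap with segmental duplications
#' (SEGDUP); penta-/hexanucleotide motifs containing homopolymer runs of
#' at least 5 resp. 6 bases in the motif or reference sequence
#' (HOMOPOLYMER); call rate below `min_call_rate` (CALLRATE); expected
#' heterozygosity below `min_het` (LOWHET, strict `<`); exact-binomial
#' heterozygosity departure from Hardy-Weinberg at `hwe_alpha` (HWE).
#' A locus passes iff no flag fires.
#'
#' @param loci data.frame with columns `id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `motif`, `period`, and optionally `ref_seq`.
#' @param genotypes list (one element per locus row) of n x 2 allele
#'   matrices with sample rownames; `NA` marks missing.
#' @param segdup_bed optional data.frame from [read_bed()].
#' @param quads optional pedigree data.frame; adds a `mendelian_rate`
#'   column (not a filter).
#' @param min_call_rate,min_het,hwe_alpha filter thresholds.
#' @return data.frame, one row per locus: `id`, `call_rate`,
#'   `expected_het`, `hwe_p`, `mendelian_rate`, `filter_flags`
#'   (comma-separated), `pass`.
#' @export
apply_locus_filters <- function(loci, genotypes, segdup_bed = NULL,
                                quads = NULL, min_call_rate = 0.80,
                                min_het = 0.095, hwe_alpha = 0.01) {
  stopifnot(nrow(loci) == length(genotypes))
  res <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    gt <- genotypes[[i]]
    n <- nrow(gt)
    called <- !is.na(gt[, 1]) & !is.na(gt[, 2])
    call_rate <- mean(called)
    flags <- character(0)

    if (.overlaps_bed(loci$chrom[i], loci$start[i], loci$end[i], segdup_bed))
      flags <- c(flags, "SEGDUP")
    per <- loci$period[i]
    if (per %in% c(5L, 6L)) {
      run <- max(.max_homopolymer_run(loci$motif[i]),
                 if ("ref_seq" %in% names(loci))
                   .max_homopolymer_run(loci$ref_seq[i]) else 0L)
      if (run >= per) flags <- c(flags, "HOMOPOLYMER")
    }
    if (call_rate < min_call_rate) flags <- c(flags, "CALLRATE")

    alleles <- c(gt[called, 1], gt[called, 2])
    if (length(alleles) > 0) {
      tab <- table(alleles)
      freqs <- as.numeric(tab) / sum(tab)
      h <- expected_heterozygosity(freqs)
      n_het <- sum(gt[called, 1] != gt[called, 2])
      hwe_p <- hwe_het_test(n_het, sum(called) - n_het, freqs)
    } else {
      h <- NA_real_
      hwe_p <- NA_real_
    }
    if (!is.na(h) && h < min_het) flags <- c(flags, "LOWHET")
    if (!is.na(hwe_p) && hwe_p < hwe_alpha) flags <- c(flags, "HWE")

    mend <- if (!is.null(quads)) mendelian_rate(quads, gt) else NA_real_
    res[[i]] <- data.frame(id = loci$id[i], call_rate = call_rate,
                           expected_het = h, hwe_p = hwe_p,
                           mendelian_rate = mend,
                           filter_flags = paste(flags, collapse = ","),
                           pass = length(flags) == 0,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}
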