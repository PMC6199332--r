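#' Founder haplotype constructor
#'
#' An ancestral SNP background on which a pathogenic repeat expansion
#' arose: ordered marker ids with one risk allele per marker. Alleles are
#' normalised to uppercase; the declared strand of the definition file is
#' taken as given.
#'
#' @param markers character vector of marker ids.
#' @param alleles character vector of risk alleles (one base per marker).
#' @return An object of class `founder_haplotype`.
#' @export
founder_haplotype <- function(markers, alleles) {
  if (length(markers) != length(alleles))
    stop("one allele per marker required")
  if (anyDuplicated(markers)) stop("duplicate marker ids")
  structure(list(markers = as.character(markers),
                 alleles = toupper(as.character(alleles))),
            class = "founder_haplotype")
}

#' The DRPLA (ATN1 CAG repeat) founder haplotype
#'
#' Nine-marker risk haplotype on which the dentatorubral-pallidoluysian
#' atrophy expansion likely originated: rs4963516, rs1007924, rs7310941,
#' rs7303722, rs2239167, rs34199021, rs2071075, rs2071076, rs2159887 with
#' alleles G, A, G, T, A, A, T, C, C.
#'
#' @return A [founder_haplotype()].
#' @export
drpla_founder <- function() {
  founder_haplotype(
    c("rs4963516", "rs1007924", "rs7310941", "rs7303722", "rs2239167",
      "rs34199021", "rs2071075", "rs2071076", "rs2159887"),
    c("G", "A", "G", "T", "A", "A", "T", "C", "C"))
}

#' Read a founder haplotype definition from a 2-column TSV
#'
#' @param path TSV with columns marker id and risk allele (no header).
#' @return A [founder_haplotype()].
#' @export
read_founder_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("founder TSV needs 2 columns: marker, allele")
  founder_haplotype(df[[1]], df[[2]])
}

#' Hamming distance of a haplotype to a founder haplotype
#'
#' Number of founder markers at which the haplotype's allele differs from
#' the risk allele. Every founder marker must be present; haplotypes with
#' a missing marker are rejected rather than imputed.
#'
#' @param haplotype named character vector of alleles (names = marker
#'   ids), or a character matrix with marker ids as column names for many
#'   haplotypes at once.
#' @param founder a [founder_haplotype()].
#' @return Integer mismatch count (vector for matrix input).
#' @export
hamming_to_founder <- function(haplotype, founder) {
  stopifnot(inherits(founder, "founder_haplotype"))
  if (is.matrix(haplotype)) {
    return(vapply(seq_len(nrow(haplotype)), function(i) {
      v <- haplotype[i, ]
      names(v) <- colnames(haplotype)
      hamming_to_founder(v, founder)
    }, integer(1)))
  }
  absent <- setdiff(founder$markers, names(haplotype))
  if (length(absent) > 0)
    stop("marker absent from haplotype: ", paste(absent, collapse = ", "))
  sum(toupper(haplotype[founder$markers]) != founder$alleles)
}

#' Correlation of STR length with distance to the founder haplotype
#'
#' Pearson correlation (with two-sided p-value) between per-haplotype STR
#' lengths and Hamming distances to the founder, plus per-distance length
#' summaries. A negative correlation indicates that haplotypes closer to
#' the founder background carry longer repeats.
#'
#' @param lengths numeric STR lengths, one per haplotype.
#' @param distances integer Hamming distances, parallel to `lengths`.
#' @return list with `r`, `p_value`, `n`, and `by_distance` (data.frame
#'   of n/mean/median length per distance).
#' @export
length_distance_correlation <- function(lengths, distances) {
  ok <- !is.na(lengths) & !is.na(distances)
  lengths <- lengths[ok]; distances <- distances[ok]
  if (length(lengths) < 3) stop("need >= 3 haplotypes")
  if (stats::var(lengths) == 0 || stats::var(distances) == 0)
    stop("zero variance in lengths or distances")
  ct <- stats::cor.test(lengths, distances)
  by <- do.call(rbind, lapply(sort(unique(distances)), function(d) {
    l <- lengths[distances == d]
    data.frame(distance = d, n = length(l), mean_length = mean(l),
               median_length = stats::median(l))
  }))
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n = length(lengths), by_distance = by)
}

#' Simulate haplotype drift away from a founder expansion background
#'
#' Each haplotype gets an age `u ~ Unif(0, 1)`; it accumulates
#' `Poisson(u * marker_rate)` marker mismatches (capped at the marker
#' count) and its repeat contracts by `Poisson(u * contraction_rate)`
#' units from the expanded founder length, emulating decay of both the
#' SNP background and the repeat along the mutation path. Older
#' haplotypes are therefore both further from the founder and shorter.
#'
#' @param founder a [founder_haplotype()].
#' @param n_haplotypes number of haplotypes to draw.
#' @param expanded_units founder repeat length in repeat units.
#' @param marker_rate expected marker mutations at age 1.
#' @param contraction_rate expected repeat-unit contraction at age 1.
#' @param seed integer RNG seed.
#' @return list with `haplotypes` (character matrix, columns = founder
#'   markers) and `lengths` (repeat units).
#' @export
simulate_founder_drift <- function(founder, n_haplotypes = 240,
                                   expanded_units = 20, marker_rate = 4,
                                   contraction_rate = 6, seed = 1L) {
  stopifnot(inherits(founder, "founder_haplotype"))
  set.seed(as.integer(seed))
  m <- length(founder$markers)
  bases <- c("A", "C", "G", "T")
  haps <- matrix(rep(founder$alleles, each = n_haplotypes),
                 nrow = n_haplotypes,
                 dimnames = list(NULL, founder$markers))
  u <- stats::runif(n_haplotypes)
  n_mut <- pmin(stats::rpois(n_haplotypes, u * marker_rate), m)
  for (i in seq_len(n_haplotypes)) {
    if (n_mut[i] == 0) next
    at <- sample.int(m, n_mut[i])
    for (j in at)
      haps[i, j] <- sample(setdiff(bases, haps[i, j]), 1L)
  }
  lengths <- expanded_units - stats::rpois(n_haplotypes,
                                           u * contraction_rate)
  list(haplotypes = haps, lengths = lengths)
}
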