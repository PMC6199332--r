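# --- transmission phasing of quad parents ------------------------------

# alleles a parent could have transmitted to a child at one site, given
# the mate's genotype (NA alleles leave the mate unconstrained)
.transmissible <- function(child, parent, mate) {
  if (anyNA(child) || anyNA(parent)) return(NULL)
  out <- numeric(0)
  for (ordv in list(child, rev(child))) {
    x <- ordv[1]; y <- ordv[2]
    if (x %in% parent && (anyNA(mate) || y %in% mate))
      out <- c(out, x)
  }
  unique(out)
}

# phase one parent of one family across sites; hap1 = allele transmitted
# to child1; returns list(h1, h2, resolution)
.phase_parent <- function(P, Q, K1, K2, pos) {
  nsite <- length(pos)
  h1 <- rep(NA_real_, nsite)
  h2 <- rep(NA_real_, nsite)
  res <- rep("missing", nsite)
  for (s in seq_len(nsite)) {
    p <- c(P[1, s], P[2, s])
    if (anyNA(p)) next
    q <- c(Q[1, s], Q[2, s])
    tx <- .transmissible(c(K1[1, s], K1[2, s]), p, q)
    tx2 <- .transmissible(c(K2[1, s], K2[2, s]), p, q)
    # a present child that cannot receive any allele from this parent is
    # Mendelian-inconsistent regardless of parental zygosity
    if ((!is.null(tx) && length(tx) == 0) ||
        (!is.null(tx2) && length(tx2) == 0)) {
      res[s] <- "mendel_error"
      next
    }
    if (p[1] == p[2]) {
      h1[s] <- p[1]; h2[s] <- p[2]; res[s] <- "hom"
      next
    }
    if (is.null(tx) || length(tx) > 1) { res[s] <- "ambiguous"; next }
    h1[s] <- tx
    h2[s] <- p[-match(tx, p)]
    res[s] <- "transmission"
  }
  # linkage pass: resolve ambiguous het sites against the nearest
  # transmission-resolved het site using child2's inherited hap index
  amb <- which(res == "ambiguous")
  anchors <- which(res == "transmission" & h1 != h2)
  for (s in amb) {
    p <- sort(c(P[1, s], P[2, s]))
    pick <- p  # default ordering: smaller allele first
    res[s] <- "default"
    if (length(anchors) > 0) {
      t <- anchors[which.min(abs(pos[anchors] - pos[s]))]
      tx2t <- .transmissible(c(K2[1, t], K2[2, t]),
                             c(P[1, t], P[2, t]), c(Q[1, t], Q[2, t]))
      if (length(tx2t) == 1) {
        e2 <- if (tx2t == h1[t]) 1L else 2L
        tx2s <- .transmissible(c(K2[1, s], K2[2, s]), p,
                               c(Q[1, s], Q[2, s]))
        ok1 <- p[e2] %in% tx2s          # hap1 = p[1]
        ok2 <- rev(p)[e2] %in% tx2s     # hap1 = p[2]
        if (ok1 != ok2) {
          pick <- if (ok1) p else rev(p)
          res[s] <- "linkage"
        }
      }
    }
    h1[s] <- pick[1]; h2[s] <- pick[2]
  }
  list(h1 = h1, h2 = h2, resolution = res)
}

#' Phase quad parents by Mendelian transmission
#'
#' Resolves parental phase at each site from transmission to the children:
#' haplotype 1 of each parent is defined as the allele transmitted to
#' child1. Sites where transmission gives a unique assignment are phased
#' directly; remaining ambiguous heterozygous sites are phased by linkage
#' with the nearest transmission-resolved heterozygous site via child2's
#' inherited-haplotype index, with any residual tie taking the smaller
#' allele first. Mendelian-inconsistent sites are set missing for that
#' family and counted.
#'
#' @param genotypes a `str_genotypes` object containing all quad members.
#' @param quads pedigree data.frame (`family`, `father`, `mother`,
#'   `child1`, `child2`).
#' @return A phased `str_genotypes` over the parent samples only, with
#'   attributes `resolution` (sites x parents character matrix) and
#'   `n_mendel_errors`.
#' @export
phase_quads_by_transmission <- function(genotypes, quads) {
  stopifnot(inherits(genotypes, "str_genotypes"))
  miss <- setdiff(unlist(quads[, c("father", "mother", "child1", "child2")]),
                  genotypes$samples)
  if (length(miss) > 0)
    stop("unknown sample in pedigree: ", paste(miss, collapse = ", "))
  pos <- genotypes$sites$pos
  parents <- c(rbind(quads$father, quads$mother))
  np <- length(parents)
  H1 <- matrix(NA_real_, np, nrow(genotypes$sites))
  H2 <- matrix(NA_real_, np, nrow(genotypes$sites))
  resol <- matrix(NA_character_, nrow(genotypes$sites), np,
                  dimnames = list(genotypes$sites$id, parents))
  pair <- function(id) rbind(genotypes$A1[id, ], genotypes$A2[id, ])
  n_err <- 0L
  for (f in seq_len(nrow(quads))) {
    Fg <- pair(quads$father[f]); Mg <- pair(quads$mother[f])
    K1 <- pair(quads$child1[f]); K2 <- pair(quads$child2[f])
    pf <- .phase_parent(Fg, Mg, K1, K2, pos)
    pm <- .phase_parent(Mg, Fg, K1, K2, pos)
    # a Mendelian-inconsistent site is dropped for the whole family
    bad <- pf$resolution == "mendel_error" | pm$resolution == "mendel_error"
    n_err <- n_err + sum(bad)
    pf$h1[bad] <- pf$h2[bad] <- pm$h1[bad] <- pm$h2[bad] <- NA_real_
    i <- (f - 1L) * 2L
    H1[i + 1L, ] <- pf$h1; H2[i + 1L, ] <- pf$h2
    H1[i + 2L, ] <- pm$h1; H2[i + 2L, ] <- pm$h2
    resol[, i + 1L] <- pf$resolution
    resol[, i + 2L] <- pm$resolution
  }
  out <- new_str_genotypes(genotypes$sites, H1, H2, parents, phased = TRUE)
  attr(out, "resolution") <- resol
  attr(out, "n_mendel_errors") <- n_err
  if (n_err > 0)
    message(n_err, " Mendelian-inconsistent family-site pairs set missing")
  out
}

# --- reference panel construction --------------------------------------

# fill missing STR alleles from haplotypes sharing the longest exact SNP
# match, SNPs ordered nearest-first from the STR (LD decays with distance)
.fill_str_alleles <- function(H, sites) {
  sc <- which(sites$type == "str")
  snp_idx <- which(sites$type == "snp")
  ordn <- snp_idx[order(abs(sites$pos[snp_idx] - sites$pos[sc]))]
  str_al <- H[, sc]
  need <- which(is.na(str_al))
  known <- which(!is.na(str_al))
  for (i in need) {
    depth <- 0L
    cand <- known
    for (j in ordn) {
      if (is.na(H[i, j])) break
      nxt <- cand[H[cand, j] == H[i, j]]
      if (length(nxt) == 0) break
      cand <- nxt
      depth <- depth + 1L
    }
    tab <- table(str_al[cand])
    best <- as.numeric(names(tab)[tab == max(tab)])
    H[i, sc] <- min(best)
  }
  H
}

#' Build a phased SNP-STR reference panel from phased parents
#'
#' Stacks the two phased haplotypes of every (unrelated) parent into a
#' panel. Residual missing STR alleles are filled with the most frequent
#' STR allele among haplotypes sharing the longest exact SNP match
#' (nearest SNPs first); residual missing SNP alleles are filled with the
#' site's major allele so that every haplotype is fully resolved.
#'
#' @param phased a phased `str_genotypes` object (parents only), e.g. from
#'   [phase_quads_by_transmission()].
#' @return A [hap_panel()].
#' @export
build_reference_panel <- function(phased) {
  stopifnot(inherits(phased, "str_genotypes"))
  if (!phased$phased) stop("input genotypes must be phased")
  nsam <- length(phased$samples)
  nsite <- nrow(phased$sites)
  H <- matrix(NA_real_, 2L * nsam, nsite)
  H[seq(1L, 2L * nsam, by = 2L), ] <- phased$A1
  H[seq(2L, 2L * nsam, by = 2L), ] <- phased$A2
  samples <- rep(phased$samples, each = 2L)
  # major-allele fill at SNP sites
  for (j in which(phased$sites$type == "snp")) {
    na <- is.na(H[, j])
    if (any(na)) {
      maj <- if (mean(H[!na, j]) > 0.5) 1 else 0
      H[na, j] <- if (all(na)) 0 else maj
    }
  }
  sc <- which(phased$sites$type == "str")
  if (all(is.na(H[, sc])))
    stop("no observed STR alleles: region has no usable STR")
  H <- .fill_str_alleles(H, phased$sites)
  hap_panel(phased$sites, H, samples)
}

# --- haplotype-matching imputation -------------------------------------

# weighted mismatch scores of one target SNP haplotype against all panel
# haplotypes; snp alleles are 0/1
.mismatch_scores <- function(target_snps, panel_snps, w) {
  as.numeric(abs(sweep(panel_snps, 2L, target_snps, `-`)) %*% w)
}

#' Impute one STR allele into a phased SNP haplotype
#'
#' Scores every panel haplotype by the weighted SNP mismatch count over a
#' window around the STR, with weight `1 / (1 + distance_to_STR_in_kb)`
#' per SNP, and copies the STR allele of the minimum-score haplotype.
#' Score ties are resolved to the most frequent STR allele among the tied
#' haplotypes, then to the smallest allele.
#'
#' @param target named numeric vector of phased SNP alleles (0/1), names =
#'   SNP site ids overlapping the panel.
#' @param panel a [hap_panel()].
#' @param window_kb window half-width around the STR start (default 50).
#' @return list with `allele` (bp offset, `NA` if no overlapping SNP),
#'   `score` (best weighted mismatch), `n_tied`.
#' @export
impute_str <- function(target, panel, window_kb = 50) {
  sc <- str_site_index(panel)
  str_pos <- panel$sites$pos[sc]
  snp_idx <- snp_site_index(panel)
  in_win <- abs(panel$sites$pos[snp_idx] - str_pos) <= window_kb * 1000
  snp_idx <- snp_idx[in_win]
  use <- snp_idx[panel$sites$id[snp_idx] %in% names(target)]
  if (length(use) == 0) {
    warning("no overlapping SNPs between target and panel window")
    return(list(allele = NA_real_, score = NA_real_, n_tied = 0L))
  }
  tvec <- target[panel$sites$id[use]]
  ok <- !is.na(tvec)
  use <- use[ok]; tvec <- tvec[ok]
  if (length(use) == 0) {
    warning("no overlapping SNPs between target and panel window")
    return(list(allele = NA_real_, score = NA_real_, n_tied = 0L))
  }
  w <- 1 / (1 + abs(panel$sites$pos[use] - str_pos) / 1000)
  scores <- .mismatch_scores(tvec, panel$H[, use, drop = FALSE], w)
  best <- min(scores)
  tied <- which(scores <= best + 1e-12)
  al <- panel_str_alleles(panel)[tied]
  tab <- table(al)
  cand <- as.numeric(names(tab)[tab == max(tab)])
  list(allele = min(cand), score = best, n_tied = length(tied))
}

#' Leave-one-out imputation over a reference panel
#'
#' For each sample: its two haplotypes are removed from the panel, its STR
#' genotype is masked, and each of its phased SNP haplotypes is imputed
#' against the reduced panel. Imputation is deterministic given the panel.
#'
#' @param panel a [hap_panel()] with at least 3 samples.
#' @param window_kb window half-width around the STR (default 50).
#' @return data.frame with one row per sample: `sample`, observed alleles
#'   `obs_a`/`obs_b`, imputed alleles `imp_a`/`imp_b` (pairs sorted).
#' @export
leave_one_out <- function(panel, window_kb = 50) {
  ids <- unique(panel$samples)
  if (length(ids) < 3)
    stop("leave-one-out needs a panel with >= 3 samples")
  sc <- str_site_index(panel)
  str_pos <- panel$sites$pos[sc]
  snp_idx <- snp_site_index(panel)
  in_win <- abs(panel$sites$pos[snp_idx] - str_pos) <= window_kb * 1000
  snp_idx <- snp_idx[in_win]
  if (length(snp_idx) == 0) stop("no SNPs within the imputation window")
  w <- 1 / (1 + abs(panel$sites$pos[snp_idx] - str_pos) / 1000)
  X <- panel$H[, snp_idx, drop = FALSE]
  str_al <- panel_str_alleles(panel)
  # all-pairs weighted mismatch: for 0/1 alleles |x - x'| = x + x' - 2xx'
  xw <- X %*% diag(w, nrow = length(w))
  S <- matrix(rowSums(xw), nrow(X), nrow(X)) +
       matrix(rowSums(xw), nrow(X), nrow(X), byrow = TRUE) -
       2 * (xw %*% t(X))
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    own <- which(panel$samples == ids[k])
    keep <- setdiff(seq_len(nrow(X)), own)
    imp <- vapply(own, function(i) {
      sc_row <- S[i, keep]
      best <- min(sc_row)
      tied <- keep[sc_row <= best + 1e-9]
      tab <- table(str_al[tied])
      min(as.numeric(names(tab)[tab == max(tab)]))
    }, numeric(1))
    obs <- sort(str_al[own])
    out[[k]] <- data.frame(sample = ids[k], obs_a = obs[1], obs_b = obs[2],
                           imp_a = min(imp), imp_b = max(imp),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
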