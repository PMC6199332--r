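# --- VCF export / import of SNP-STR panels -----------------------------

.vcf_header <- function(chrom, samples) {
  c("##fileformat=VCFv4.2",
    "##source=strpanel",
    paste0("##contig=<ID=", chrom, ">"),
    "##INFO=<ID=MOTIF,Number=1,Type=String,Description=\"STR motif\">",
    "##INFO=<ID=PERIOD,Number=1,Type=Integer,Description=\"Motif length in bp\">",
    "##INFO=<ID=REFLEN,Number=1,Type=Integer,Description=\"Reference STR allele length in bp\">",
    "##INFO=<ID=OFFSETS,Number=A,Type=Integer,Description=\"ALT allele length offsets from the reference in bp\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

# one VCF body line; a1/a2 are per-sample allele *indices* (NA = missing)
.vcf_line <- function(chrom, pos, id, ref, alt, info, a1, a2, sep) {
  g1 <- ifelse(is.na(a1), ".", a1)
  g2 <- ifelse(is.na(a2), ".", a2)
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", info, "GT",
          paste0(g1, sep, g2)), collapse = "\t")
}

# allele columns -> VCF index encoding for one site row of `sites`
.site_record <- function(sites, s, a1, a2, sep) {
  if (sites$type[s] == "snp") {
    return(.vcf_line(sites$chrom[s], sites$pos[s], sites$id[s],
                     "A", "C", ".", a1, a2, sep))
  }
  offs <- sort(setdiff(unique(stats::na.omit(c(a1, a2))), 0))
  alt <- if (length(offs) == 0) "." else
    paste0("<STR", seq_along(offs), ">", collapse = ",")
  info <- paste0("MOTIF=", sites$motif[s], ";PERIOD=", sites$period[s],
                 ";REFLEN=", sites$reflen[s],
                 if (length(offs)) paste0(";OFFSETS=",
                                          paste(offs, collapse = ",")))
  idx <- function(a) ifelse(is.na(a), NA_integer_,
                            ifelse(a == 0, 0L, match(a, offs)))
  .vcf_line(sites$chrom[s], sites$pos[s], sites$id[s], "N", alt, info,
            idx(a1), idx(a2), sep)
}

#' Write a phased haplotype panel to VCF
#'
#' SNP records use REF/ALT single bases with phased GT (`|`); the STR
#' record is symbolic multi-allelic with INFO keys MOTIF, PERIOD, REFLEN
#' and OFFSETS (per-ALT bp length offsets from the reference allele).
#' Coordinates are 1-based.
#'
#' @param panel a [hap_panel()].
#' @param path output path (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "hap_panel"))
  ids <- unique(panel$samples)
  i1 <- match(ids, panel$samples)            # first haplotype per sample
  i2 <- length(panel$samples) - match(ids, rev(panel$samples)) + 1L
  lines <- .vcf_header(panel$sites$chrom[1], ids)
  for (s in seq_len(nrow(panel$sites)))
    lines <- c(lines, .site_record(panel$sites, s,
                                   panel$H[i1, s], panel$H[i2, s], "|"))
  writeLines(lines, path)
  invisible(path)
}

#' Write diploid genotypes to VCF
#'
#' Same record layout as [write_panel_vcf()]; the GT separator is `|` for
#' phased and `/` for unphased genotypes, and missing STR calls are
#' emitted as `./.`.
#'
#' @param genotypes a `str_genotypes` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "str_genotypes"))
  sep <- if (genotypes$phased) "|" else "/"
  lines <- .vcf_header(genotypes$sites$chrom[1], genotypes$samples)
  for (s in seq_len(nrow(genotypes$sites)))
    lines <- c(lines, .site_record(genotypes$sites, s,
                                   genotypes$A1[, s], genotypes$A2[, s],
                                   sep))
  writeLines(lines, path)
  invisible(path)
}

.parse_info_field <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
  if (length(m) == 0) return(NA_character_)
  sub(paste0("^;?", key, "="), "", m)
}

# read a VCF written by this package into sites + allele matrices
.read_strpanel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  info <- fix[, "INFO"]
  is_str <- !is.na(info) & grepl("MOTIF=", info)
  sites <- data.frame(id = fix[, "ID"], chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      type = ifelse(is_str, "str", "snp"),
                      motif = NA_character_, period = NA_integer_,
                      reflen = NA_integer_, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, names(gt)))
  phased <- all(grepl("\\|", gt[1, ]))
  parts <- strsplit(as.character(gt), "[|/]")
  a1 <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  a2 <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  A1 <- matrix(a1, nrow(gt), ncol(gt))
  A2 <- matrix(a2, nrow(gt), ncol(gt))
  for (s in which(is_str)) {
    sites$motif[s] <- .parse_info_field(info[s], "MOTIF")
    sites$period[s] <- as.integer(.parse_info_field(info[s], "PERIOD"))
    sites$reflen[s] <- as.integer(.parse_info_field(info[s], "REFLEN"))
    offs <- .parse_info_field(info[s], "OFFSETS")
    offs <- if (is.na(offs)) numeric(0) else
      as.numeric(strsplit(offs, ",")[[1]])
    map <- function(a) {
      out <- rep(NA_real_, length(a))
      out[!is.na(a) & a == 0] <- 0
      k <- !is.na(a) & a > 0
      out[k] <- offs[a[k]]
      out
    }
    A1[s, ] <- map(A1[s, ])
    A2[s, ] <- map(A2[s, ])
  }
  list(sites = sites, A1 = t(A1), A2 = t(A2), samples = colnames(gt),
       phased = phased)
}

#' Read a phased SNP-STR panel from VCF
#'
#' Inverse of [write_panel_vcf()]: STR allele indices are mapped back to
#' bp offsets through the INFO OFFSETS key.
#'
#' @param path path to a VCF written by [write_panel_vcf()].
#' @return A [hap_panel()].
#' @export
read_panel_vcf <- function(path) {
  d <- .read_strpanel_vcf(path)
  if (!d$phased) stop("panel VCF must be phased (| separator)")
  nsam <- length(d$samples)
  H <- matrix(NA_real_, 2L * nsam, nrow(d$sites))
  H[seq(1L, 2L * nsam, 2L), ] <- d$A1
  H[seq(2L, 2L * nsam, 2L), ] <- d$A2
  hap_panel(d$sites, H, rep(d$samples, each = 2L))
}

#' Read diploid genotypes from VCF
#'
#' @param path path to a VCF written by [write_genotypes_vcf()].
#' @return A `str_genotypes` object.
#' @export
read_genotypes_vcf <- function(path) {
  d <- .read_strpanel_vcf(path)
  new_str_genotypes(d$sites, d$A1, d$A2, d$samples, d$phased)
}

# --- PED pedigree ------------------------------------------------------

#' Write quad pedigrees to a 6-column PED file
#'
#' Columns: family, individual, father, mother, sex (father 1, mother 2,
#' children 0 = unknown), phenotype (0).
#'
#' @param quads data.frame with `family`, `father`, `mother`, `child1`,
#'   `child2`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(quads, path) {
  rows <- character(0)
  for (f in seq_len(nrow(quads))) {
    q <- quads[f, ]
    rows <- c(rows,
      paste(q$family, q$father, 0, 0, 1, 0, sep = "\t"),
      paste(q$family, q$mother, 0, 0, 2, 0, sep = "\t"),
      paste(q$family, q$child1, q$father, q$mother, 0, 0, sep = "\t"),
      paste(q$family, q$child2, q$father, q$mother, 0, 0, sep = "\t"))
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read quad pedigrees from a PED file
#'
#' Reconstructs one quad per family id; families without exactly two
#' parents and two children are rejected.
#'
#' @param path path to a 6-column PED file.
#' @return data.frame with `family`, `father`, `mother`, `child1`,
#'   `child2`.
#' @export
read_ped <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("family", "id", "father", "mother",
                                        "sex", "phenotype"))
  out <- lapply(split(df, df$family), function(fam) {
    kids <- fam$id[fam$father != "0"]
    pars <- fam$id[fam$father == "0"]
    if (length(kids) != 2 || length(pars) != 2)
      stop("family ", fam$family[1], " is not a quad")
    fa <- unique(fam$father[fam$father != "0"])
    mo <- unique(fam$mother[fam$mother != "0"])
    if (length(fa) != 1 || length(mo) != 1)
      stop("family ", fam$family[1], " has inconsistent parent ids")
    data.frame(family = fam$family[1], father = fa, mother = mo,
               child1 = kids[1], child2 = kids[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[unique(df$family)])
  rownames(out) <- NULL
  out
}

# --- YAML simulation config --------------------------------------------

#' Write a simulation configuration to YAML
#'
#' @param config a [sim_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' @param path path to a YAML file written by [write_config_yaml()].
#' @return A validated [sim_config()].
#' @export
read_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sim_config, vals[!vapply(vals, is.null, logical(1))])
}
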