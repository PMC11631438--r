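# Phased genotype container: an ordered site table plus per-haplotype allele
# matrices (0 = ref, 1 = alt, NA = missing) and optional allele-depth matrices.
# hap1/hap2 order is meaningful only for phased individuals.

#' Construct a phased genotype matrix
#'
#' @param sites Tibble with columns `chrom`, `pos` (0-based), `ref`, `alt`,
#'   and optionally `panel_af` (population alternate-allele frequency, `NA`
#'   when unknown).
#' @param hap1,hap2 Integer matrices (sites x individuals) of 0/1/NA allele
#'   calls; column names are individual ids.
#' @param ad_ref,ad_alt Optional integer matrices of per-site reference and
#'   alternate read depths, same shape as `hap1`.
#' @param phased Named logical: whether each individual's hap1/hap2 assignment
#'   is a true haplotype phase. Defaults to `TRUE` for all.
#' @return A `kin_geno` object.
#' @export
genotype_matrix <- function(sites, hap1, hap2, ad_ref = NULL, ad_alt = NULL,
                            phased = NULL) {
  sites <- as_tibble(sites)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  if (!"panel_af" %in% names(sites)) sites$panel_af <- NA_real_
  stopifnot(is.matrix(hap1), is.matrix(hap2),
            nrow(hap1) == nrow(sites), nrow(hap2) == nrow(sites),
            identical(colnames(hap1), colnames(hap2)))
  # strictly increasing positions within chromosome
  ok <- tapply(sites$pos, factor(sites$chrom, levels = unique(sites$chrom)),
               function(p) all(diff(p) > 0))
  if (!all(unlist(ok))) abort("site positions must be strictly increasing within each chromosome")
  samples <- colnames(hap1)
  if (is.null(phased)) phased <- setNames(rep(TRUE, length(samples)), samples)
  structure(
    list(sites = sites, hap1 = hap1, hap2 = hap2,
         ad_ref = ad_ref, ad_alt = ad_alt,
         phased = phased[samples]),
    class = "kin_geno"
  )
}

#' @export
print.kin_geno <- function(x, ...) {
  cat("<kin_geno> ", nrow(x$sites), " sites x ", ncol(x$hap1),
      " individuals (", paste(head(colnames(x$hap1), 6), collapse = ", "),
      if (ncol(x$hap1) > 6) ", ..." else "", ")\n", sep = "")
  cat("  chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  cat("  allele depths:", if (is.null(x$ad_ref)) "absent" else "present", "\n")
  invisible(x)
}

#' Individuals present in a genotype matrix
#' @param geno A `kin_geno`.
#' @return Character vector of ids.
#' @export
geno_samples <- function(geno) colnames(geno$hap1)

geno_check_sample <- function(geno, id) {
  missing <- setdiff(id, geno_samples(geno))
  if (length(missing) > 0) {
    abort(paste0("individual(s) not in genotype matrix: ",
                 paste(missing, collapse = ", ")))
  }
  invisible(id)
}

# Diploid dosage (0/1/2, NA if either haplotype missing) for one individual.
geno_dosage <- function(geno, id) {
  geno_check_sample(geno, id)
  geno$hap1[, id] + geno$hap2[, id]
}

#' Genotypes as a tidy tibble
#'
#' One row per site per individual, with haplotype alleles, dosage, and
#' allele depths when available.
#'
#' @param geno A `kin_geno`.
#' @param individuals Ids to include (default all).
#' @return A tibble.
#' @export
geno_tidy <- function(geno, individuals = geno_samples(geno)) {
  geno_check_sample(geno, individuals)
  map_dfr(individuals, function(id) {
    out <- geno$sites
    out$individual <- id
    out$hap1 <- geno$hap1[, id]
    out$hap2 <- geno$hap2[, id]
    out$dosage <- out$hap1 + out$hap2
    if (!is.null(geno$ad_ref)) {
      out$ad_ref <- geno$ad_ref[, id]
      out$ad_alt <- geno$ad_alt[, id]
    }
    out
  })
}

# Row indices of sites on a chromosome.
geno_chrom_idx <- function(geno, chrom) which(geno$sites$chrom == chrom)
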