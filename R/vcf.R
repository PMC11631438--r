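# Native VCF v4.2 reading/writing for biallelic SNVs with GT (+ optional AD).
# VCF positions are 1-based; the container is 0-based half-open throughout,
# so pos = POS - 1 on the way in and POS = pos + 1 on the way out.

#' Read genotypes from a VCF file
#'
#' Retains biallelic SNV records only; multi-allelic and indel records are
#' skipped (counts reported via a message). `GT` is required; `AD` populates
#' allele depths when present. A `|` genotype separator marks an individual
#' as phased at that record; an individual is treated as phased overall only
#' if every non-missing genotype is phased. The INFO key `AF=` (or `PANEL_AF=`)
#' fills `panel_af`.
#'
#' @param path Path to an uncompressed VCF file.
#' @return A `kin_geno`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1) abort("malformed VCF: expected a single #CHROM header line")
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10) abort("VCF has no sample columns")
  samples <- cols[10:length(cols)]
  body <- lines[seq_along(lines) > hdr]
  body <- body[nzchar(body)]
  if (length(body) == 0) abort("VCF contains no records")

  fields <- strsplit(body, "\t", fixed = TRUE)
  mat <- do.call(rbind, fields)
  ref <- mat[, 4]; alt <- mat[, 5]
  snv <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!snv)
  if (n_skip > 0) {
    inform(paste0("read_vcf: skipped ", n_skip,
                  " non-SNV/multiallelic record(s)"))
  }
  mat <- mat[snv, , drop = FALSE]
  if (nrow(mat) == 0) abort("VCF contains no biallelic SNV records")

  fmt <- strsplit(mat[, 9], ":", fixed = TRUE)
  gt_idx <- map_int(fmt, ~ match("GT", .x))
  if (anyNA(gt_idx)) abort("VCF record(s) missing GT in FORMAT")
  ad_idx <- map_int(fmt, ~ match("AD", .x) %||% NA_integer_)

  af <- stringr::str_match(mat[, 8], "(?:^|;)(?:PANEL_)?AF=([0-9.eE+-]+)")[, 2]

  n_sites <- nrow(mat)
  n_ind <- length(samples)
  hap1 <- matrix(NA_integer_, n_sites, n_ind, dimnames = list(NULL, samples))
  hap2 <- hap1
  ad_ref <- hap1; ad_alt <- hap1
  phase_ok <- matrix(TRUE, n_sites, n_ind)
  have_ad <- FALSE

  allele_int <- function(a) ifelse(a == "0", 0L, ifelse(a == "1", 1L, NA_integer_))
  for (j in seq_len(n_ind)) {
    sample_fields <- strsplit(mat[, 9 + j], ":", fixed = TRUE)
    gt <- map2(sample_fields, gt_idx, ~ .x[[.y]])
    gt <- unlist(gt)
    phased_here <- grepl("|", gt, fixed = TRUE)
    parts <- stringr::str_split_fixed(gt, "[/|]", 2)
    hap1[, j] <- allele_int(parts[, 1])
    hap2[, j] <- allele_int(parts[, 2])
    phase_ok[, j] <- phased_here | is.na(hap1[, j])
    ad <- map2(sample_fields, ad_idx,
               ~ if (is.na(.y) || length(.x) < .y) NA_character_ else .x[[.y]])
    ad <- unlist(ad)
    has <- !is.na(ad) & ad != "." & ad != ""
    if (any(has)) {
      have_ad <- TRUE
      adp <- stringr::str_split_fixed(ad[has], ",", 2)
      ad_ref[has, j] <- suppressWarnings(as.integer(adp[, 1]))
      ad_alt[has, j] <- suppressWarnings(as.integer(adp[, 2]))
    }
  }

  sites <- tibble(
    chrom = mat[, 1],
    pos = as.double(mat[, 2]) - 1,
    ref = ref[snv],
    alt = alt[snv],
    panel_af = suppressWarnings(as.double(af))
  )
  ord <- order(factor(sites$chrom, levels = unique(sites$chrom)), sites$pos)
  genotype_matrix(
    sites[ord, ],
    hap1[ord, , drop = FALSE], hap2[ord, , drop = FALSE],
    ad_ref = if (have_ad) ad_ref[ord, , drop = FALSE] else NULL,
    ad_alt = if (have_ad) ad_alt[ord, , drop = FALSE] else NULL,
    phased = setNames(apply(phase_ok, 2, all), samples)
  )
}

#' Write genotypes to a VCF file
#'
#' Emits a minimal VCF v4.2 with phased `GT` (`|` for phased individuals,
#' `/` otherwise), `AD` when depths are present, and `AF` in INFO when
#' `panel_af` is known.
#'
#' @param geno A `kin_geno`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  samples <- geno_samples(geno)
  sep <- ifelse(geno$phased[samples], "|", "/")
  has_ad <- !is.null(geno$ad_ref)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Panel alternate allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_ad) "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  a1 <- ifelse(is.na(geno$hap1), ".", geno$hap1)
  a2 <- ifelse(is.na(geno$hap2), ".", geno$hap2)
  gt <- matrix(paste0(a1, rep(sep, each = nrow(a1)), a2),
               nrow = nrow(a1), dimnames = dimnames(geno$hap1))
  if (has_ad) {
    ad <- matrix(
      ifelse(is.na(geno$ad_ref), ".",
             paste0(geno$ad_ref, ",", geno$ad_alt)),
      nrow = nrow(a1)
    )
    gt <- matrix(paste0(gt, ":", ad), nrow = nrow(a1))
  }
  info <- ifelse(is.na(geno$sites$panel_af), ".",
                 paste0("AF=", signif(geno$sites$panel_af, 6)))
  recs <- paste(
    geno$sites$chrom, format(geno$sites$pos + 1, scientific = FALSE, trim = TRUE),
    ".", geno$sites$ref, geno$sites$alt, ".", "PASS", info,
    if (has_ad) "GT:AD" else "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(recs, con)
  invisible(path)
}
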