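# DNM calling: Mendelian violations against real and/or surrogate parents
# inside accessible regions, the filter stack, spectrum classification,
# parent-of-origin phasing, rate estimation and VAF screening.

#' Classify a substitution into the six 1-mer classes
#'
#' Collapses purine-ancestral changes onto the opposite strand so the
#' ancestral allele is C or A. Vectorised.
#'
#' @param ref,alt Single-base reference and alternate alleles.
#' @return Character vector of classes from [mutation_types()].
#' @examples
#' classify_spectrum("G", "T")  # "C>A"
#' classify_spectrum("T", "C")  # "A>G"
#' @export
classify_spectrum <- function(ref, alt) {
  bases <- c("A", "C", "G", "T")
  if (!all(ref %in% bases) || !all(alt %in% bases)) {
    abort("ref and alt must be single bases A/C/G/T")
  }
  if (any(ref == alt)) abort("ref and alt must differ")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- ref %in% c("G", "T")
  r <- ifelse(flip, comp[ref], ref)
  a <- ifelse(flip, comp[alt], alt)
  unname(paste0(r, ">", a))
}

#' Call candidate DNMs as Mendelian violations
#'
#' Emits a candidate at every site inside the accessible regions where the
#' proband is heterozygous and every named (real or surrogate) parent is
#' homozygous for the reference allele. Requiring surrogates to be homozygous
#' reference polarises the call: a site where the surrogate sibling carries
#' the allele can never be reported as a DNM in the proband.
#'
#' @param geno A `kin_geno`.
#' @param proband Proband id.
#' @param parents Character vector of real and/or surrogate parent ids.
#' @param regions A `kin_regions` for this configuration.
#' @return A `kin_calls` tibble: `proband`, `chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `vaf`, `alt_hap` (which proband haplotype carries the alternate
#'   allele; `NA` if unphased), `spectrum_class`, `phase`, filter flag columns
#'   (all `FALSE`) and `pass` (`NA` until [apply_site_filters()]).
#' @export
call_mendelian_violations <- function(geno, proband, parents, regions) {
  if (length(parents) == 0) abort("parents must name at least one individual")
  geno_check_sample(geno, c(proband, parents))
  stopifnot(inherits(regions, "kin_regions"))
  p1 <- geno$hap1[, proband]
  p2 <- geno$hap2[, proband]
  dos <- p1 + p2
  missing_geno <- is.na(dos)
  if (any(missing_geno)) {
    inform(paste0("call_mendelian_violations: ", sum(missing_geno),
                  " site(s) with missing proband genotype skipped"))
  }
  hom_ref <- rep(TRUE, length(dos))
  for (p in parents) {
    hom_ref <- hom_ref &
      !is.na(geno$hap1[, p]) & geno$hap1[, p] == 0L &
      !is.na(geno$hap2[, p]) & geno$hap2[, p] == 0L
  }
  in_region <- iv_contains(regions$regions, geno$sites$chrom, geno$sites$pos)
  idx <- which(!missing_geno & dos == 1L & hom_ref & in_region)
  sites <- geno$sites[idx, ]
  depth <- vaf <- rep(NA_real_, length(idx))
  if (!is.null(geno$ad_ref)) {
    depth <- geno$ad_ref[idx, proband] + geno$ad_alt[idx, proband]
    vaf <- ifelse(depth > 0, geno$ad_alt[idx, proband] / depth, NA_real_)
  }
  alt_hap <- if (isTRUE(geno$phased[proband])) {
    ifelse(p1[idx] == 1L, 1L, 2L)
  } else {
    rep(NA_integer_, length(idx))
  }
  calls <- tibble(
    proband = proband,
    chrom = sites$chrom, pos = sites$pos,
    ref = sites$ref, alt = sites$alt,
    depth = depth, vaf = vaf,
    alt_hap = alt_hap,
    spectrum_class = if (length(idx)) classify_spectrum(sites$ref, sites$alt) else character(),
    phase = "unknown",
    filter_panel = FALSE, filter_shared = FALSE,
    filter_cluster = FALSE, filter_vaf = FALSE,
    pass = NA
  )
  class(calls) <- c("kin_calls", class(calls))
  calls
}

#' Apply the DNM filter stack
#'
#' Marks (never deletes) each candidate with:
#' * `filter_panel` — the site segregates in the population panel
#'   (`panel_af > 0`); such variants were plausibly inherited from a missing
#'   parent rather than arising de novo.
#' * `filter_shared` — the same variant is carried by two or more pedigree
#'   members who are not in a parent-child relationship (a transmitted DNM is
#'   exempt); shared variants are usually inherited through mis-inferred IBD
#'   or created by gene conversion.
#' * `filter_cluster` — the call belongs to a chained group (transitive
#'   closure of pairwise distance <= `cluster_span_bp`) of more than
#'   `cluster_count` calls containing at least one known variant.
#' * `filter_vaf` — variant allele fraction below `min_vaf`; calls without
#'   allele depths pass with a warning.
#'
#' `pass` becomes `TRUE` for calls with no flag set; downstream counts and
#' rates use passing calls only.
#'
#' @param calls A `kin_calls` tibble.
#' @param geno The `kin_geno` the calls came from.
#' @param ped A `kin_pedigree` covering the genotyped individuals.
#' @param min_vaf Minimum variant allele fraction.
#' @param cluster_count Cluster size above which a known-variant-anchored
#'   chain is removed.
#' @param cluster_span_bp Chaining distance for the cluster filter.
#' @param panel_filter Apply the population-panel filter?
#' @param known_sites Optional tibble (`chrom`, `pos`) of externally annotated
#'   known variants (e.g. rsID-bearing sites); sites with `panel_af > 0`
#'   always count as known.
#' @return `calls` with filter flags and `pass` filled in.
#' @export
apply_site_filters <- function(calls, geno, ped, min_vaf = 0.30,
                               cluster_count = 6, cluster_span_bp = 50,
                               panel_filter = TRUE, known_sites = NULL) {
  if (nrow(calls) == 0) {
    calls$pass <- logical(0)
    return(calls)
  }
  site_key <- paste(geno$sites$chrom, geno$sites$pos)
  call_idx <- match(paste(calls$chrom, calls$pos), site_key)

  af <- geno$sites$panel_af[call_idx]
  calls$filter_panel <- panel_filter & !is.na(af) & af > 0

  # familial sharing: carriers of the alt among all genotyped individuals
  samples <- geno_samples(geno)
  dos <- geno$hap1[call_idx, , drop = FALSE] + geno$hap2[call_idx, , drop = FALSE]
  calls$filter_shared <- map_dbl(seq_len(nrow(calls)), function(k) {
    carriers <- samples[!is.na(dos[k, ]) & dos[k, ] >= 1L]
    if (length(carriers) < 2) return(0)
    pairs <- utils::combn(carriers, 2, simplify = FALSE)
    any(!map_dbl(pairs, ~ is_parent_child(ped, .x[1], .x[2])))
  }) > 0

  # cluster filter: transitive chaining within cluster_span_bp
  known <- calls$filter_panel | (!is.na(af) & af > 0)
  if (!is.null(known_sites) && nrow(known_sites) > 0) {
    known <- known | paste(calls$chrom, calls$pos) %in%
      paste(known_sites$chrom, known_sites$pos)
  }
  calls$filter_cluster <- FALSE
  for (ch in unique(calls$chrom)) {
    sel <- which(calls$chrom == ch)
    ord <- sel[order(calls$pos[sel])]
    if (length(ord) < 2) next
    gaps <- diff(calls$pos[ord])
    grp <- cumsum(c(1, gaps > cluster_span_bp))
    for (g in unique(grp)) {
      members <- ord[grp == g]
      if (length(members) > cluster_count && any(known[members])) {
        calls$filter_cluster[members] <- TRUE
      }
    }
  }

  no_ad <- is.na(calls$vaf)
  if (any(no_ad)) {
    warn(paste0("apply_site_filters: ", sum(no_ad),
                " call(s) lack allele depths; VAF filter not applied to them"))
  }
  calls$filter_vaf <- !no_ad & calls$vaf < min_vaf

  calls$pass <- !(calls$filter_panel | calls$filter_shared |
                    calls$filter_cluster | calls$filter_vaf)
  calls
}

#' Phase DNM calls to parent of origin
#'
#' A call is `"paternal"` when the alternate allele sits on a proband
#' haplotype covered by a sibling-shared segment labelled paternal (shared
#' with the surrogate father but not with the mother), `"maternal"` when that
#' haplotype lies in a maternal-labelled segment, and `"unknown"` otherwise —
#' including the fully surrogate (two-surrogate) configuration, where segment
#' origins are themselves unknown, and unphased calls.
#'
#' @param calls A `kin_calls` tibble with `alt_hap` filled.
#' @param segments Classified segment tibble involving the proband.
#' @return `calls` with `phase` filled in.
#' @export
phase_dnm <- function(calls, segments) {
  if (nrow(calls) == 0) return(calls)
  calls$phase <- map_dbl(seq_len(nrow(calls)), function(k) {
    hap <- calls$alt_hap[k]
    if (is.na(hap)) return(0)
    pb <- calls$proband[k]
    fwd <- segments$id_a == pb & segments$hap_a == hap
    rev <- segments$id_b == pb & segments$hap_b == hap
    cover <- (fwd | rev) &
      segments$chrom == calls$chrom[k] &
      segments$start <= calls$pos[k] & segments$end > calls$pos[k]
    origins <- unique(segments$origin[cover])
    origins <- setdiff(origins, "unknown")
    if (length(origins) != 1) return(0)
    if (origins == "paternal") 2 else if (origins == "maternal") 1 else 0
  }) |>
    (\(code) c("unknown", "maternal", "paternal")[code + 1])()
  calls
}

#' Estimate the per-generation mutation rate from passing calls
#'
#' Rate = passing calls / (2 x accessible bp): DNMs can arise on either of
#' the two haplotypes spanning the accessible region.
#'
#' @param calls A filtered `kin_calls` tibble.
#' @param regions The `kin_regions` the calls were made in.
#' @return A one-row tibble: `proband`, `n_pass`, `accessible_bp`,
#'   `rate_per_bp_per_generation`.
#' @export
estimate_rate <- function(calls, regions) {
  stopifnot(inherits(regions, "kin_regions"))
  if (regions$total_bp <= 0) abort("accessible region set is empty; rate undefined")
  n_pass <- sum(calls$pass %in% TRUE)
  tibble(
    proband = regions$proband,
    n_pass = n_pass,
    accessible_bp = regions$total_bp,
    rate_per_bp_per_generation = n_pass / (2 * regions$total_bp)
  )
}

#' Screen an individual's VAF distribution for somatic contamination
#'
#' Germline heterozygous DNMs sit on one of two haplotypes, so their VAFs
#' centre on 0.5; a median VAF below `flag_threshold` suggests an excess of
#' somatic (sub-clonal) mutation calls and flags the individual.
#'
#' @param calls A `kin_calls` tibble for one individual.
#' @param flag_threshold Median-VAF threshold below which to flag.
#' @return A one-row tibble: `proband`, `n`, `median_vaf`, `flagged`.
#' @export
screen_vaf_distribution <- function(calls, flag_threshold = 0.40) {
  v <- calls$vaf[!is.na(calls$vaf) & !is.na(calls$depth) & calls$depth > 0]
  if (length(v) == 0) {
    warn("screen_vaf_distribution: no calls with depth > 0; nothing to screen")
    return(tibble(proband = if (nrow(calls)) calls$proband[1] else NA_character_,
                  n = 0L, median_vaf = NA_real_, flagged = FALSE))
  }
  med <- median(v)
  tibble(proband = calls$proband[1], n = length(v),
         median_vaf = med, flagged = med < flag_threshold)
}

#' Write / read DNM calls as TSV
#' @param calls A `kin_calls` tibble.
#' @param path File path.
#' @return `path` invisibly; `read_calls_tsv` returns the calls tibble.
#' @export
write_calls_tsv <- function(calls, path) {
  readr::write_tsv(as_tibble(calls), path)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    proband = "c", chrom = "c", pos = "d", ref = "c", alt = "c",
    depth = "d", vaf = "d", alt_hap = "i", spectrum_class = "c",
    phase = "c", filter_panel = "l", filter_shared = "l",
    filter_cluster = "l", filter_vaf = "l", pass = "l"
  ))
  class(x) <- c("kin_calls", class(x))
  x
}
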