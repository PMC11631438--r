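# Accessible-region geometry: which parts of a proband's genome permit DNM
# calling under a given configuration of real and surrogate parents.

#' Theoretical callable fraction of the genome
#'
#' In a family with one sequenced parent and `n` surrogate siblings, a locus
#' is callable iff at least one sibling inherited the same missing-parent
#' haplotype as the proband, giving an expected callable fraction of
#' 1 - 2^-n. With no sequenced parents, both of the proband's haplotypes must
#' independently be covered, giving (1 - 2^-n)^2. With both parents present
#' the whole autosomal genome is callable.
#'
#' @param n_surrogate_sibs Number of siblings available as surrogates (>= 0).
#' @param n_real_parents Number of sequenced real parents (0, 1 or 2).
#' @return Callable fraction in \[0, 1\].
#' @examples
#' theoretical_callable_fraction(2, 1) # mother + three children: 3/4
#' theoretical_callable_fraction(1, 1) # mother + two children: 1/2
#' theoretical_callable_fraction(1, 0) # no parents, one surrogate: 1/4
#' @export
theoretical_callable_fraction <- function(n_surrogate_sibs, n_real_parents = 1) {
  if (any(n_surrogate_sibs < 0)) abort("n_surrogate_sibs must be >= 0")
  stopifnot(all(n_real_parents %in% 0:2))
  one <- 1 - 2^(-n_surrogate_sibs)
  dplyr::case_when(
    n_real_parents == 2 ~ 1,
    n_real_parents == 1 ~ one,
    TRUE ~ one^2
  )
}

# Intervals where the proband shares the given haplotype (1/2) with sibling
# `sib`, from a classified segment tibble; optionally restricted to an origin.
proband_hap_intervals <- function(segments, proband, sib, hap,
                                  origin = NULL) {
  s <- segments
  fwd <- s$id_a == proband & s$id_b == sib & s$hap_a == hap
  rev <- s$id_b == proband & s$id_a == sib & s$hap_b == hap
  s <- s[fwd | rev, , drop = FALSE]
  if (!is.null(origin)) s <- s[s$origin %in% origin, , drop = FALSE]
  if (nrow(s) == 0) return(iv_empty())
  iv_reduce(s[, c("chrom", "start", "end")])
}

# Intervals where proband shares either haplotype with sib (optional origin).
proband_shared_intervals <- function(segments, proband, sib, origin = NULL) {
  iv_union(
    proband_hap_intervals(segments, proband, sib, 1, origin),
    proband_hap_intervals(segments, proband, sib, 2, origin)
  )
}

#' Regions accessible for DNM calling under a parent configuration
#'
#' @param proband Proband id.
#' @param segments Classified IBD segment tibble (see
#'   [classify_parental_origin()]); may involve several sibling pairs.
#' @param layout Genome layout (gives chromosome lengths, hence the callable
#'   fraction denominator).
#' @param real_mother,real_father Ids of sequenced real parents, or `NULL`.
#' @param surrogate_fathers Sibling ids standing in for a missing father
#'   (used with a real mother, or as one pool of a two-surrogate design).
#' @param surrogate_mothers Sibling ids standing in for a missing mother.
#'   In a fully surrogate design the mother/father designation is arbitrary;
#'   the convention here (and in [designate_surrogates()]) is deterministic.
#' @return A `kin_regions` object: list with `proband`, `configuration`,
#'   `regions` (interval tibble), `total_bp`, `genome_bp`, `callable_fraction`.
#' @details
#' * Both real parents: the whole autosomal genome.
#' * One real parent + surrogate siblings: the union over surrogates of
#'   segments attributed to the missing parent (paternal-origin segments when
#'   the mother is real, maternal-origin when the father is real).
#' * No real parents: the union over (surrogate mother i, surrogate father j)
#'   of regions where the proband shares one haplotype with i and the other
#'   with j; i = j gives double-surrogate regions where both haplotypes are
#'   shared with the same sibling.
#'
#' No eligible surrogate yields an empty region set, not an error.
#' @export
accessible_regions <- function(proband, segments, layout,
                               real_mother = NULL, real_father = NULL,
                               surrogate_fathers = character(),
                               surrogate_mothers = character()) {
  genome_bp <- layout_total_bp(layout)
  config <- list(
    real_parents = c(real_mother, real_father),
    surrogate_mothers = surrogate_mothers,
    surrogate_fathers = surrogate_fathers
  )
  if (!is.null(real_mother) && !is.null(real_father)) {
    regions <- layout_intervals(layout)
  } else if (!is.null(real_mother) || !is.null(real_father)) {
    surrogates <- if (!is.null(real_mother)) surrogate_fathers else surrogate_mothers
    want_origin <- if (!is.null(real_mother)) "paternal" else "maternal"
    regions <- iv_empty()
    for (s in surrogates) {
      regions <- iv_union(
        regions,
        proband_shared_intervals(segments, proband, s, origin = want_origin)
      )
    }
  } else {
    regions <- iv_empty()
    for (i in surrogate_mothers) {
      s1_i <- proband_hap_intervals(segments, proband, i, 1)
      s2_i <- proband_hap_intervals(segments, proband, i, 2)
      for (j in surrogate_fathers) {
        s1_j <- proband_hap_intervals(segments, proband, j, 1)
        s2_j <- proband_hap_intervals(segments, proband, j, 2)
        regions <- iv_union(regions, iv_intersect(s1_i, s2_j))
        regions <- iv_union(regions, iv_intersect(s2_i, s1_j))
      }
    }
  }
  regions <- iv_intersect(regions, layout_intervals(layout))
  new_regions(proband, config, regions, genome_bp)
}

new_regions <- function(proband, config, regions, genome_bp) {
  total_bp <- iv_total_bp(regions)
  structure(
    list(proband = proband, configuration = config,
         regions = regions, total_bp = total_bp, genome_bp = genome_bp,
         callable_fraction = total_bp / genome_bp),
    class = "kin_regions"
  )
}

#' @export
print.kin_regions <- function(x, ...) {
  cat("<kin_regions> proband ", x$proband, ": ", nrow(x$regions),
      " region(s), ", format(x$total_bp, big.mark = ","), " bp (",
      sprintf("%.1f%%", 100 * x$callable_fraction), " of genome)\n", sep = "")
  invisible(x)
}

#' Deterministic surrogate mother/father designation
#'
#' In a fully surrogate configuration the mother/father roles are arbitrary;
#' this helper assigns them deterministically: the lexicographically smallest
#' id becomes a surrogate mother, and all ids serve in both pools so every
#' ordered pairing (including the double-surrogate case i = j) is explored.
#'
#' @param ids Surrogate sibling ids.
#' @return List with `surrogate_mothers` and `surrogate_fathers`.
#' @export
designate_surrogates <- function(ids) {
  ids <- sort(ids)
  list(surrogate_mothers = ids, surrogate_fathers = ids)
}

#' Excise high-density Mendelian-violation windows from accessible regions
#'
#' Clusters of Mendelian violations betray mis-inferred IBD boundaries (the
#' "violations" are polymorphic differences between distinct parental
#' haplotypes, not DNMs). Windows of `window_bp`, slid in steps of half a
#' window, containing more than `max_violations` candidate sites are excised
#' together with a `margin_bp` flank on each side.
#'
#' @param regions A `kin_regions`.
#' @param candidates Tibble of candidate positions with columns `chrom`, `pos`.
#' @param window_bp Window size in bp.
#' @param max_violations Maximum tolerated candidates per window.
#' @param margin_bp Extra flank excised around an offending window.
#' @return A new `kin_regions` with offending windows removed and an
#'   `excised` attribute holding the removed intervals.
#' @export
density_filter <- function(regions, candidates, window_bp = 1e5,
                           max_violations = 3, margin_bp = 1e4) {
  stopifnot(inherits(regions, "kin_regions"))
  excised <- iv_empty()
  if (nrow(candidates) > 0 && nrow(regions$regions) > 0) {
    step <- max(1, floor(window_bp / 2))
    bad <- list()
    for (k in seq_len(nrow(regions$regions))) {
      reg <- regions$regions[k, ]
      pos <- sort(candidates$pos[candidates$chrom == reg$chrom &
                                   candidates$pos >= reg$start &
                                   candidates$pos < reg$end])
      if (length(pos) <= max_violations) next
      starts <- seq(reg$start, max(reg$start, reg$end - 1), by = step)
      for (ws in starts) {
        we <- min(ws + window_bp, reg$end)
        n_in <- sum(pos >= ws & pos < we)
        if (n_in > max_violations) {
          bad[[length(bad) + 1]] <- tibble(
            chrom = reg$chrom,
            start = max(reg$start, ws - margin_bp),
            end = min(reg$end, we + margin_bp)
          )
        }
      }
    }
    if (length(bad) > 0) excised <- iv_reduce(bind_rows(bad))
  }
  out <- new_regions(
    regions$proband, regions$configuration,
    iv_setdiff(regions$regions, excised), regions$genome_bp
  )
  attr(out, "excised") <- excised
  out
}

#' Write accessible regions as BED3 plus a JSON sidecar
#'
#' @param regions A `kin_regions`.
#' @param prefix Output path prefix; writes `<prefix>.bed` and
#'   `<prefix>.json` (configuration, total bp, callable fraction).
#' @return Paths, invisibly.
#' @export
write_regions <- function(regions, prefix) {
  bed <- paste0(prefix, ".bed")
  js <- paste0(prefix, ".json")
  readr::write_tsv(
    regions$regions |>
      mutate(start = format(.data$start, scientific = FALSE, trim = TRUE),
             end = format(.data$end, scientific = FALSE, trim = TRUE)),
    bed, col_names = FALSE
  )
  jsonlite::write_json(
    list(proband = regions$proband,
         configuration = regions$configuration,
         total_bp = regions$total_bp,
         genome_bp = regions$genome_bp,
         callable_fraction = regions$callable_fraction),
    js, auto_unbox = TRUE, digits = NA
  )
  invisible(c(bed, js))
}

#' Read accessible regions back from BED3 + JSON sidecar
#' @param prefix Path prefix used by [write_regions()].
#' @return A `kin_regions`.
#' @export
read_regions <- function(prefix) {
  bed <- readr::read_tsv(paste0(prefix, ".bed"),
                         col_names = c("chrom", "start", "end"),
                         col_types = "cdd")
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  new_regions(meta$proband, meta$configuration, bed, meta$genome_bp)
}
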