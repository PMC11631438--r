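# Sibling IBD inference: a native match-run scanner over retained common
# markers, with hap-IBD-style run merging across short gaps, plus
# parental-origin labelling of the shared haplotypes.

#' Infer IBD segments between two phased siblings
#'
#' Scans each of the four haplotype pairings (proband hap x sibling hap) for
#' maximal runs of matching alleles over retained common markers
#' (minor allele frequency > `min_maf`). Runs on the same pairing separated
#' by a span of at most `max_gap_bp` are merged, tolerating isolated
#' discordant markers from genotype error. Segments shorter than
#' `min_length_bp` or supported by fewer than `min_markers` markers are
#' dropped.
#'
#' @param geno A `kin_geno`; both individuals must be phased.
#' @param pair Character vector of two individual ids.
#' @param min_maf Minimum minor allele frequency for a marker to be used.
#' @param max_gap_bp Maximum bp span between match runs that are merged.
#' @param min_length_bp Minimum segment length in bp.
#' @param min_markers Minimum number of supporting matching markers.
#' @return Tibble of segments: `id_a`, `hap_a`, `id_b`, `hap_b`, `chrom`,
#'   `start`, `end` (0-based half-open), `n_markers`, `origin`
#'   (`"unknown"` until [classify_parental_origin()] is applied).
#' @export
infer_sibling_ibd <- function(geno, pair, min_maf = 0.10, max_gap_bp = 1000,
                              min_length_bp = 2e6, min_markers = 100) {
  stopifnot(length(pair) == 2)
  geno_check_sample(geno, pair)
  unphased <- pair[!geno$phased[pair]]
  if (length(unphased) > 0) {
    abort(paste0(
      "individual(s) not phased: ", paste(unphased, collapse = ", "),
      ". Phase with an external tool or use the simulator's truth phase."
    ))
  }
  maf <- pmin(geno$sites$panel_af, 1 - geno$sites$panel_af)
  if (all(is.na(maf))) abort("sites carry no panel_af; cannot select common markers")
  keep <- !is.na(maf) & maf > min_maf
  out <- list()
  for (ch in unique(geno$sites$chrom)) {
    idx <- which(keep & geno$sites$chrom == ch)
    if (length(idx) == 0) next
    pos <- geno$sites$pos[idx]
    for (ha in 1:2) {
      va <- (if (ha == 1) geno$hap1 else geno$hap2)[idx, pair[1]]
      for (hb in 1:2) {
        vb <- (if (hb == 1) geno$hap1 else geno$hap2)[idx, pair[2]]
        m <- !is.na(va) & !is.na(vb) & va == vb
        segs <- match_runs(m, pos, max_gap_bp)
        if (nrow(segs) == 0) next
        segs$hap_a <- ha
        segs$hap_b <- hb
        segs$chrom <- ch
        out[[length(out) + 1]] <- segs
      }
    }
  }
  if (length(out) == 0) return(empty_segments())
  res <- bind_rows(out)
  res <- res[res$end - res$start >= min_length_bp & res$n_markers >= min_markers, ]
  if (nrow(res) == 0) return(empty_segments())
  tibble(
    id_a = pair[1], hap_a = res$hap_a, id_b = pair[2], hap_b = res$hap_b,
    chrom = res$chrom, start = res$start, end = res$end,
    n_markers = res$n_markers, origin = "unknown"
  ) |>
    arrange(.data$chrom, .data$start)
}

empty_segments <- function() {
  tibble(id_a = character(), hap_a = integer(), id_b = character(),
         hap_b = integer(), chrom = character(), start = double(),
         end = double(), n_markers = integer(), origin = character())
}

# Maximal runs of TRUE in `m` over marker positions `pos`, merging runs whose
# intervening span is <= max_gap_bp. Returns start/end (half-open bp, ends one
# past the last matching marker) and the matching-marker count per run.
match_runs <- function(m, pos, max_gap_bp) {
  if (!any(m)) return(tibble(start = double(), end = double(), n_markers = integer()))
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- tibble(
    i = starts[r$values], j = ends[r$values]
  )
  runs$start <- pos[runs$i]
  runs$end <- pos[runs$j] + 1
  runs$n_markers <- runs$j - runs$i + 1
  if (nrow(runs) == 1) return(runs[, c("start", "end", "n_markers")])
  # merge consecutive runs across short spans
  merged <- runs[1, ]
  for (k in 2:nrow(runs)) {
    gap <- runs$start[k] - merged$end[nrow(merged)]
    if (gap <= max_gap_bp) {
      merged$end[nrow(merged)] <- runs$end[k]
      merged$n_markers[nrow(merged)] <- merged$n_markers[nrow(merged)] + runs$n_markers[k]
    } else {
      merged <- bind_rows(merged, runs[k, ])
    }
  }
  merged[, c("start", "end", "n_markers")]
}

#' Label IBD segments with parental origin
#'
#' For full siblings, the haplotype they share over a segment was inherited
#' either from their mother or from their father. When the mother's genotypes
#' are available the segment is labelled `"maternal"` if the shared haplotype
#' is consistent with the maternal genome: a retained marker conflicts when
#' the shared allele is absent from the mother's genotype, and a segment with
#' at most `conflict_threshold` conflicting markers is maternal. Segments
#' conflicting more often match neither maternal haplotype and are labelled
#' `"paternal"`. With `mother = NULL` every segment is `"unknown"` and
#' double-surrogate logic must be used downstream.
#'
#' Per-marker consistency (rather than whole-segment identity to one maternal
#' haplotype) keeps labels stable when the mother's own meiosis recombined
#' her two haplotypes inside the segment.
#'
#' @param segments Segment tibble from [infer_sibling_ibd()].
#' @param geno A `kin_geno` containing the siblings (and mother if given).
#' @param mother Mother's individual id, or `NULL` if unavailable.
#' @param min_maf Markers used for labelling (same retention rule as the scan).
#' @param conflict_threshold Maximum tolerated fraction of conflicting markers
#'   for a maternal label.
#' @return `segments` with `origin` filled in.
#' @export
classify_parental_origin <- function(segments, geno, mother = NULL,
                                     min_maf = 0.10, conflict_threshold = 0.01) {
  if (nrow(segments) == 0) return(segments)
  if (is.null(mother)) {
    segments$origin <- "unknown"
    return(segments)
  }
  geno_check_sample(geno, mother)
  maf <- pmin(geno$sites$panel_af, 1 - geno$sites$panel_af)
  keep <- !is.na(maf) & maf > min_maf
  m1 <- geno$hap1[, mother]
  m2 <- geno$hap2[, mother]
  segments$origin <- map_dbl(seq_len(nrow(segments)), function(k) {
    seg <- segments[k, ]
    idx <- which(keep & geno$sites$chrom == seg$chrom &
                   geno$sites$pos >= seg$start & geno$sites$pos < seg$end)
    if (length(idx) == 0) return(NA_real_)
    child <- (if (seg$hap_a == 1) geno$hap1 else geno$hap2)[idx, seg$id_a]
    ok <- !is.na(child) & !(is.na(m1[idx]) & is.na(m2[idx]))
    if (!any(ok)) return(NA_real_)
    conflict <- child[ok] != m1[idx][ok] & child[ok] != m2[idx][ok]
    mean(conflict, na.rm = TRUE)
  }) |>
    (\(fr) dplyr::case_when(
      is.na(fr) ~ "unknown",
      fr <= conflict_threshold ~ "maternal",
      TRUE ~ "paternal"
    ))()
  segments
}

#' Read / write hap-IBD-style segment TSV
#'
#' Columns: id1, hap1, id2, hap2, chrom, start, end, n_markers. Coordinates
#' on disk are 0-based half-open (matching the package's internal convention).
#'
#' @param path File path.
#' @return For `read_ibd_tsv`, a segment tibble (origin `"unknown"`).
#' @export
read_ibd_tsv <- function(path) {
  x <- readr::read_tsv(path, col_names = c("id_a", "hap_a", "id_b", "hap_b",
                                           "chrom", "start", "end", "n_markers"),
                       col_types = "cicicddi", comment = "#")
  x$origin <- "unknown"
  x
}

#' @rdname read_ibd_tsv
#' @param segments Segment tibble.
#' @export
write_ibd_tsv <- function(segments, path) {
  readr::write_tsv(
    segments[, c("id_a", "hap_a", "id_b", "hap_b", "chrom", "start", "end", "n_markers")],
    path, col_names = FALSE
  )
  invisible(path)
}
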