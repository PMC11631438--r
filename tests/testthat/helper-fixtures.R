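# Fixtures built in code: tiny hand-constructed genotype sets and a compact
# simulated family reused across tests.

# A minimal genotype set: one 10 kb chromosome, `n` evenly spaced markers,
# all panel_af = 0.5, constructed from explicit haplotype vectors.
make_geno <- function(haps, pos = NULL, chrom = "chr1", panel_af = 0.5,
                      ad = NULL) {
  ids <- names(haps)
  n <- length(haps[[1]]$h1)
  if (is.null(pos)) pos <- seq(0, by = 1000, length.out = n)
  sites <- tibble::tibble(
    chrom = chrom, pos = as.double(pos),
    ref = rep("C", n), alt = rep("A", n),
    panel_af = rep_len(panel_af, n)
  )
  hap1 <- sapply(haps, function(h) as.integer(h$h1))
  hap2 <- sapply(haps, function(h) as.integer(h$h2))
  colnames(hap1) <- colnames(hap2) <- ids
  ad_ref <- ad_alt <- NULL
  if (!is.null(ad)) {
    dos <- hap1 + hap2
    depth <- matrix(ad, nrow(hap1), ncol(hap1))
    ad_alt <- round(depth * dos / 2)
    ad_ref <- depth - ad_alt
    colnames(ad_ref) <- colnames(ad_alt) <- ids
  }
  genotype_matrix(sites, hap1, hap2, ad_ref = ad_ref, ad_alt = ad_alt)
}

# Cached small simulated family (2 x 20 Mb, ~0.2 expected DNM scale) shared
# by caller/benchmark tests; regenerated once per test run.
small_family <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      withr::with_seed(424242, {
        cfg <- sim_config(layout = genome_layout(2, 2e7), n_children = 3,
                          marker_density = 5e-4)
        cache <<- c(simulate_family(cfg), list(config = cfg))
      })
    }
    cache
  }
})

# Brute-force interval membership over integer grids, for oracle checks.
bitmap_of <- function(iv, len) {
  m <- rep(FALSE, len)
  for (k in seq_len(nrow(iv))) {
    sel <- iv$start[k]:(iv$end[k] - 1) + 1
    m[sel] <- TRUE
  }
  m
}

expect_same_intervals <- function(a, b) {
  expect_equal(
    dplyr::arrange(a, chrom, start),
    dplyr::arrange(b, chrom, start),
    ignore_attr = TRUE
  )
}
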