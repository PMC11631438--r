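# Mendelian-violation calling, filter stack, spectrum, phasing, rates, VAF.

trio_geno <- function() {
  # 8 sites; proband het at 1,3,5; parents hom-ref everywhere except site 3
  # (mother het) and site 5 (surrogate sibling het)
  make_geno(list(
    M  = list(h1 = c(0, 0, 0, 0, 1, 0, 0, 0), h2 = rep(0, 8)),
    S  = list(h1 = c(0, 0, 0, 0, 0, 0, 1, 0), h2 = rep(0, 8)),
    P  = list(h1 = c(0, 1, 0, 0, 0, 0, 1, 0), h2 = c(0, 0, 0, 0, 1, 0, 0, 0))
  ), panel_af = 0)
}

full_region <- function(proband = "P", len = 1e6) {
  accessible_regions(proband, empty_segments(), genome_layout(1, len),
                     real_mother = "M", real_father = "F")
}

test_that("violations need proband het and all parents hom-ref, in region", {
  g <- trio_geno()
  reg <- new_regions("P", list(), tibble::tibble(chrom = "chr1", start = 0,
                                                 end = 8000), 8000)
  calls <- call_mendelian_violations(g, "P", c("M", "S"), reg)
  # site pos=1000: P het, M and S hom-ref -> candidate
  expect_true(1000 %in% calls$pos)
  # site pos=4000: mother het -> no call; pos=6000: surrogate het -> no call
  expect_false(4000 %in% calls$pos)
  expect_false(6000 %in% calls$pos)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$alt_hap, 1L)
  # restricting the region drops the call
  reg2 <- new_regions("P", list(), tibble::tibble(chrom = "chr1", start = 2000,
                                                  end = 8000), 8000)
  expect_equal(nrow(call_mendelian_violations(g, "P", c("M", "S"), reg2)), 0)
  expect_error(call_mendelian_violations(g, "P", character(), reg), "parent")
})

test_that("homozygous-alt probands are not called", {
  g <- make_geno(list(
    M = list(h1 = rep(0, 3), h2 = rep(0, 3)),
    P = list(h1 = c(0, 1, 1), h2 = c(0, 0, 1))
  ), panel_af = 0)
  reg <- new_regions("P", list(), tibble::tibble(chrom = "chr1", start = 0,
                                                 end = 3000), 3000)
  calls <- call_mendelian_violations(g, "P", "M", reg)
  expect_equal(calls$pos, 1000)   # the 1/1 site at pos 2000 is skipped
})

test_that("spectrum classification collapses to pyrimidine/A ancestral strand", {
  expect_equal(classify_spectrum("G", "T"), "C>A")
  expect_equal(classify_spectrum("T", "C"), "A>G")
  expect_equal(classify_spectrum("C", "T"), "C>T")
  expect_equal(classify_spectrum("A", "C"), "A>C")
  # strand invariance across all 12 ordered substitutions
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (r in names(comp)) for (a in names(comp)) {
    if (r == a) next
    expect_equal(classify_spectrum(r, a),
                 classify_spectrum(comp[[r]], comp[[a]]))
  }
  expect_error(classify_spectrum("C", "C"))
  expect_error(classify_spectrum("C", "CT"))
})

test_that("panel and VAF filters mark without deleting", {
  g <- trio_geno()
  g$sites$panel_af <- c(0, 0.05, 0, 0, 0, 0, 0, 0)  # candidate site is in panel
  reg <- new_regions("P", list(), tibble::tibble(chrom = "chr1", start = 0,
                                                 end = 8000), 8000)
  calls <- call_mendelian_violations(g, "P", c("M", "S"), reg)
  calls$vaf <- 0.25
  calls$depth <- 40
  ped <- pedigree(tibble::tibble(
    id = c("M", "S", "P"), sex = c("female", "unknown", "unknown"),
    mother_id = c(NA, "M", "M"), father_id = NA_character_
  ))
  out <- apply_site_filters(calls, g, ped)
  expect_equal(nrow(out), nrow(calls))   # annotate, never delete
  expect_true(all(out$filter_panel))
  expect_true(all(out$filter_vaf))       # 0.25 < 0.30
  expect_false(any(out$pass))
  # vaf exactly at threshold passes
  calls$vaf <- 0.30
  g$sites$panel_af[2] <- 0
  out2 <- apply_site_filters(calls, g, ped)
  expect_true(all(out2$pass))
})

test_that("sharing filter exempts parent-child pairs only", {
  n <- 4
  # variant present in P and aunt A (not parent-child) at site 1;
  # present in P and P's child K at site 3
  g <- make_geno(list(
    M = list(h1 = rep(0, n), h2 = rep(0, n)),
    A = list(h1 = c(1, 0, 0, 0), h2 = rep(0, n)),
    K = list(h1 = c(0, 0, 1, 0), h2 = rep(0, n)),
    P = list(h1 = c(1, 0, 1, 0), h2 = rep(0, n))
  ), panel_af = 0)
  ped <- pedigree(tibble::tibble(
    id = c("M", "A", "P", "K"),
    sex = c("female", "female", "female", "unknown"),
    mother_id = c(NA, NA, "M", "P"),
    father_id = NA_character_
  ))
  reg <- new_regions("P", list(), tibble::tibble(chrom = "chr1", start = 0,
                                                 end = 4000), 4000)
  calls <- call_mendelian_violations(g, "P", "M", reg)
  calls$vaf <- 0.5; calls$depth <- 40
  out <- apply_site_filters(calls, g, ped)
  expect_true(out$filter_shared[out$pos == 0])     # shared with aunt
  expect_false(out$filter_shared[out$pos == 2000]) # transmitted to own child
  expect_true(out$pass[out$pos == 2000])
})

test_that("cluster filter removes known-variant-anchored chains only above size", {
  mk_calls <- function(n_chain, with_known) {
    g <- make_geno(list(
      M = list(h1 = rep(0, n_chain), h2 = rep(0, n_chain)),
      P = list(h1 = rep(1, n_chain), h2 = rep(0, n_chain))
    ), pos = seq(0, by = 40, length.out = n_chain), panel_af = 0)
    reg <- new_regions("P", list(), tibble::tibble(chrom = "chr1", start = 0,
                                                   end = 1e5), 1e5)
    calls <- call_mendelian_violations(g, "P", "M", reg)
    calls$vaf <- 0.5; calls$depth <- 40
    ped <- pedigree(tibble::tibble(id = c("M", "P"), sex = "female",
                                   mother_id = c(NA, "M"),
                                   father_id = NA_character_))
    known <- if (with_known) tibble::tibble(chrom = "chr1", pos = 0) else NULL
    apply_site_filters(calls, g, ped, known_sites = known)
  }
  out7 <- mk_calls(7, TRUE)    # chain of 7 within 50 bp, one known
  expect_true(all(out7$filter_cluster))
  out6 <- mk_calls(6, TRUE)    # exactly 6: "over 6" not met
  expect_false(any(out6$filter_cluster))
  out7b <- mk_calls(7, FALSE)  # no known anchor
  expect_false(any(out7b$filter_cluster))
})

test_that("filter marking is idempotent", {
  fam <- small_family()
  reg <- accessible_regions("C1", empty_segments(), fam$config$layout,
                            real_mother = "mother", real_father = "father")
  calls <- call_mendelian_violations(fam$geno, "C1", c("mother", "father"), reg)
  once <- apply_site_filters(calls, fam$geno, fam$pedigree)
  twice <- apply_site_filters(once, fam$geno, fam$pedigree)
  expect_identical(once, twice)
})

test_that("phasing assigns parent of origin from classified segments", {
  segs <- tibble::tibble(
    id_a = c("P", "P"), hap_a = c(1L, 2L), id_b = "S", hap_b = c(1L, 2L),
    chrom = "chr1", start = c(0, 0), end = c(1e6, 1e6),
    n_markers = 100L, origin = c("maternal", "paternal")
  )
  calls <- tibble::tibble(
    proband = "P", chrom = "chr1", pos = c(100, 200, 300),
    ref = "C", alt = "A", depth = 40, vaf = 0.5,
    alt_hap = c(1L, 2L, NA), spectrum_class = "C>A", phase = "unknown",
    filter_panel = FALSE, filter_shared = FALSE, filter_cluster = FALSE,
    filter_vaf = FALSE, pass = TRUE
  )
  out <- phase_dnm(calls, segs)
  expect_equal(out$phase, c("maternal", "paternal", "unknown"))
  # two-surrogate mode: origins unknown -> phase unknown
  segs$origin <- "unknown"
  out2 <- phase_dnm(calls, segs)
  expect_true(all(out2$phase == "unknown"))
})

test_that("rate estimate divides passing calls by twice the accessible bp", {
  reg <- new_regions("P", list(), tibble::tibble(chrom = "chr1", start = 0,
                                                 end = 1e9), 1e9)
  calls <- tibble::tibble(pass = rep(TRUE, 10))
  r <- estimate_rate(calls, reg)
  expect_equal(r$rate_per_bp_per_generation, 5e-9)
  expect_equal(estimate_rate(tibble::tibble(pass = logical()),
                             reg)$rate_per_bp_per_generation, 0)
  empty <- new_regions("P", list(), iv_empty(), 1e9)
  expect_error(estimate_rate(calls, empty), "empty")
})

test_that("VAF screening flags somatic-contaminated distributions", {
  mk <- function(vafs) tibble::tibble(proband = "X", vaf = vafs,
                                      depth = rep(50, length(vafs)))
  withr::with_seed(8, {
    germline <- rbinom(1000, 50, 0.5) / 50
  })
  ok <- screen_vaf_distribution(mk(germline))
  expect_false(ok$flagged)
  expect_equal(ok$median_vaf, 0.5, tolerance = 0.02)
  bad <- screen_vaf_distribution(mk(rep(0.25, 20)))
  expect_true(bad$flagged)
  # 50/50 germline-somatic mixture is flagged at the default threshold
  withr::with_seed(9, {
    mix <- c(rbinom(500, 50, 0.5), rbinom(500, 50, 0.25)) / 50
  })
  expect_true(screen_vaf_distribution(mk(mix))$flagged)
  expect_warning(res <- screen_vaf_distribution(mk(numeric())), "no calls")
  expect_false(res$flagged)
})

test_that("calls round-trip through TSV", {
  fam <- small_family()
  reg <- accessible_regions("C1", empty_segments(), fam$config$layout,
                            real_mother = "mother", real_father = "father")
  calls <- call_mendelian_violations(fam$geno, "C1", c("mother", "father"), reg)
  calls <- apply_site_filters(calls, fam$geno, fam$pedigree)
  f <- withr::local_tempfile()
  write_calls_tsv(calls, f)
  back <- read_calls_tsv(f)
  expect_equal(as.data.frame(back), as.data.frame(calls))
})
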