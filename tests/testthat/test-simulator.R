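# Simulator: determinism, meiosis statistics, DNM planting, mutator folds,
# gene conversion, benchmarking.

test_that("same seed reproduces the simulation byte-for-byte", {
  cfg <- sim_config(layout = genome_layout(1, 5e6), n_children = 2,
                    marker_density = 2e-4)
  f1 <- withr::with_seed(77, simulate_family(cfg))
  f2 <- withr::with_seed(77, simulate_family(cfg))
  expect_identical(f1$geno$hap1, f2$geno$hap1)
  expect_identical(f1$geno$ad_alt, f2$geno$ad_alt)
  expect_identical(f1$truth$dnms, f2$truth$dnms)
})

test_that("founder marker count and heterozygosity follow the config", {
  withr::with_seed(41, {
    cfg <- sim_config(layout = genome_layout(1, 1e7), n_children = 1,
                      marker_density = 1e-3,
                      founder_freq = function(n) rep(0.5, n))
    fo <- simulate_founders(cfg)
  })
  expect_equal(nrow(fo$sites), 1e4, tolerance = 0.05)
  het <- mean(fo$hap1[, "mother"] != fo$hap2[, "mother"])
  expect_equal(het, 0.5, tolerance = 0.05)
  bad <- sim_config(layout = genome_layout(1, 100), marker_density = 1e-6)
  withr::with_seed(42, expect_error(simulate_founders(bad), "zero markers"))
})

test_that("meiosis crossover count matches the genetic map", {
  withr::with_seed(43, {
    cfg <- sim_config(layout = genome_layout(1, 1e8), n_children = 1,
                      marker_density = 1e-5)
    fo <- simulate_founders(cfg)
    # 100 Mb at 1 cM/Mb = 1 Morgan: mean one crossover per meiosis
    nbk <- replicate(300, nrow(simulate_meiosis(fo, "mother",
                                                cfg$layout)$breakpoints))
  })
  expect_equal(mean(nbk), 1.0, tolerance = 0.15)
  # zero recombination: gamete equals one parental haplotype end to end
  lay0 <- genome_layout(1, 1e6, cm_per_mb = 0)
  withr::with_seed(44, {
    cfg0 <- sim_config(layout = lay0, n_children = 1, marker_density = 1e-3)
    fo0 <- simulate_founders(cfg0)
    m <- simulate_meiosis(fo0, "father", lay0)
  })
  expect_equal(nrow(m$breakpoints), 0)
  expect_true(identical(m$alleles, unname(fo0$hap1[, "father"])) ||
                identical(m$alleles, unname(fo0$hap2[, "father"])))
})

test_that("sibling pairs share each parental haplotype over about half the genome", {
  withr::with_seed(45, ss <- sibling_sharing(400))
  expect_lt(abs(mean(ss$frac_paternal) - 0.5), 0.02)
  expect_lt(abs(mean(ss$frac_maternal) - 0.5), 0.02)
  expect_lt(abs(mean(ss$frac_both) - 0.25), 0.02)
})

test_that("planted DNM counts are Poisson around the truth expectations", {
  lay <- genome_layout(2, 1e7)   # accessibility scale 0.1 of the reference
  cfg <- sim_config(layout = lay, n_children = 5, marker_density = 1e-5)
  scale <- layout_total_bp(lay) / attr(cfg$coefficients, "reference_genome_bp")
  e <- expected_counts(cfg$coefficients, cfg$a_mat, cfg$a_pat, scale)
  withr::with_seed(46, {
    counts <- unlist(lapply(1:60, function(i) {
      fam <- simulate_family(cfg)
      table(factor(fam$truth$dnms$child, levels = paste0("C", 1:5)))
    }))
  })
  lambda <- sum(e$expected_total)
  expect_equal(mean(counts), lambda,
               tolerance = 3 * sqrt(lambda / length(counts)) / lambda)
  # zero coefficients plant nothing
  zero <- age_coefficients(
    dplyr::mutate(tibble::as_tibble(cfg$coefficients),
                  m_mat = 0, b_mat = 0, m_pat = 0, b_pat = 0), 2e8)
  cfg0 <- sim_config(layout = lay, n_children = 2, marker_density = 1e-5,
                     coefficients = zero)
  withr::with_seed(47, fam0 <- simulate_family(cfg0))
  expect_equal(nrow(fam0$truth$dnms), 0)
})

test_that("a maternal C>A mutator inflates maternal C>A counts only", {
  lay <- genome_layout(2, 1e7)
  fold <- 4
  cfg <- sim_config(layout = lay, n_children = 5, marker_density = 1e-5,
                    mutator = list(target = "maternal", type = "C>A",
                                   fold = fold))
  scale <- layout_total_bp(lay) / attr(cfg$coefficients, "reference_genome_bp")
  e <- expected_counts(cfg$coefficients, cfg$a_mat, cfg$a_pat, scale)
  withr::with_seed(48, {
    dnms <- dplyr::bind_rows(lapply(1:80, function(i) {
      simulate_family(cfg)$truth$dnms
    }))
  })
  n_children_total <- 80 * 5
  ca <- dnms[dnms$type == "C>A", ]
  mat_rate <- sum(ca$parent_of_origin == "maternal") / n_children_total
  pat_rate <- sum(ca$parent_of_origin == "paternal") / n_children_total
  em <- unname(e$expected_mat[e$type == "C>A"])
  ep <- unname(e$expected_pat[e$type == "C>A"])
  expect_equal(mat_rate / em, fold, tolerance = 0.15)
  expect_equal(pat_rate / ep, 1, tolerance = 0.15)
  expect_error(sim_config(mutator = list(target = "maternal", type = "C>A",
                                         fold = 0.5)), "fold")
})

test_that("true IBD segments partition each chromosome per sibling pair", {
  withr::with_seed(49, {
    cfg <- sim_config(layout = genome_layout(2, 2e7), n_children = 3,
                      marker_density = 1e-5)
    fam <- simulate_family(cfg)
  })
  segs <- true_ibd_segments(fam$truth, c("C1", "C3"))
  for (side in c("maternal", "paternal")) {
    s <- segs[segs$origin == side, ]
    # shared + unshared partitions: shared intervals are disjoint and within
    # the genome; complement where the pair differs
    expect_true(all(s$start < s$end))
    expect_lte(iv_total_bp(s[, c("chrom", "start", "end")]),
               layout_total_bp(cfg$layout))
  }
})

test_that("benchmark partitions false negatives and attributes false positives", {
  fam <- small_family()
  lay <- fam$config$layout
  reg_full <- accessible_regions("C1", empty_segments(), lay,
                                 real_mother = "mother", real_father = "father")
  calls <- call_mendelian_violations(fam$geno, "C1", c("mother", "father"),
                                     reg_full)
  calls <- apply_site_filters(calls, fam$geno, fam$pedigree)
  bm <- benchmark_calls(calls, fam$truth, reg_full)
  expect_equal(bm$precision, 1.0)
  expect_equal(bm$recall_in_accessible, 1.0)
  # truth DNMs outside a restricted region are inaccessible, not missed
  reg_half <- new_regions("C1", list(), tibble::tibble(
    chrom = "chr1", start = 0, end = 1e7), layout_total_bp(lay))
  calls_h <- call_mendelian_violations(fam$geno, "C1", c("mother", "father"),
                                       reg_half)
  calls_h <- apply_site_filters(calls_h, fam$geno, fam$pedigree)
  bm_h <- benchmark_calls(calls_h, fam$truth, reg_half)
  expect_equal(bm_h$fn_by_cause[["missed"]], 0)
  n_out <- sum(!iv_contains(reg_half$regions,
                            fam$truth$dnms$chrom[fam$truth$dnms$child == "C1"],
                            fam$truth$dnms$pos[fam$truth$dnms$child == "C1"]))
  expect_equal(bm_h$fn_by_cause[["inaccessible"]], n_out)
})

test_that("gene conversion produces attributable false positives when filters are off", {
  lay <- genome_layout(1, 5e6)
  cfg <- sim_config(layout = lay, n_children = 2, marker_density = 1e-3,
                    gene_conversion = list(rate = 20, tract_length_bp = 5e4))
  withr::with_seed(50, fam <- simulate_family(cfg))
  # call C1 against mother + surrogate sibling C2 over the whole genome,
  # with no sharing/panel filtering: conversions masquerade as DNMs
  reg <- new_regions("C1", list(), layout_intervals(lay), layout_total_bp(lay))
  calls <- call_mendelian_violations(fam$geno, "C1", c("mother", "C2"), reg)
  calls$pass <- TRUE
  bm <- benchmark_calls(calls, fam$truth, reg)
  expect_gt(bm$fp_by_cause[["gene_conversion"]], 0)
})

test_that("germline het VAFs center on one half at depth 50", {
  fam <- small_family()
  hets <- which(geno_dosage(fam$geno, "C1") == 1L)
  vaf <- fam$geno$ad_alt[hets, "C1"] /
    (fam$geno$ad_ref[hets, "C1"] + fam$geno$ad_alt[hets, "C1"])
  se <- sd(vaf) / sqrt(length(vaf))
  expect_lt(abs(mean(vaf) - 0.5), 3 * se + 1e-3)
})
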