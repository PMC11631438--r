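# Parental-age expectations and exact Poisson burden machinery, checked
# against brute-force pmf summation oracles.

# independent oracle: P(X >= k) by direct pmf summation in log space
tail_oracle <- function(k, lambda, upper = 500) {
  if (k == 0) return(1)
  sum(exp(k:upper * log(lambda) - lambda - lgamma(k:upper + 1)))
}

demo_coeffs <- function() {
  age_coefficients(tibble::tibble(
    type = mutation_types(),
    m_mat = c(0.5, 0.1, 0.2, 0.1, 0.3, 0.1),
    b_mat = c(2, 1, 0, 1, 2, 0.5),
    m_pat = c(1.0, 0.4, 0.9, 0.3, 0.8, 0.2),
    b_pat = c(3, 2, 1, 0.5, 2, 1)
  ), reference_genome_bp = 2.7e9)
}

test_that("expected counts are linear in age and scale multiplicatively", {
  co <- demo_coeffs()
  e <- expected_counts(co, 30, 30)
  expect_equal(e$expected_mat[e$type == "C>A"], 0.5 * 30 + 2)  # m*a + b
  expect_equal(e$expected_total, e$expected_mat + e$expected_pat)
  half <- expected_counts(co, 30, 30, accessibility_scale = 0.5)
  expect_equal(half$expected_total, e$expected_total / 2)
  zero <- age_coefficients(
    dplyr::mutate(tibble::as_tibble(co), m_mat = 0, b_mat = 0,
                  m_pat = 0, b_pat = 0), 2.7e9)
  expect_true(all(expected_counts(zero, 30, 30)$expected_total == 0))
  # negative model values are floored with a warning
  neg <- age_coefficients(
    dplyr::mutate(tibble::as_tibble(co), b_mat = -100), 2.7e9)
  expect_warning(en <- expected_counts(neg, 30, 30), "floored")
  expect_true(all(en$expected_mat == 0))
})

test_that("coefficient validation demands all six types and round-trips TSV", {
  expect_error(age_coefficients(tibble::as_tibble(demo_coeffs())[1:5, ], 1e9),
               "six mutation types")
  f <- withr::local_tempfile()
  write_age_coefficients(demo_coeffs(), f)
  back <- read_age_coefficients(f)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(demo_coeffs()),
               ignore_attr = TRUE)
  expect_equal(attr(back, "reference_genome_bp"), 2.7e9)
})

test_that("poisson upper tail matches pmf-summation oracle", {
  expect_equal(poisson_upper_tail(0, 5), 1)
  expect_equal(poisson_upper_tail(10, 5), tail_oracle(10, 5), tolerance = 1e-10)
  for (lam in c(0.5, 2, 10)) {
    for (k in c(0, 1, 3, 8, 20)) {
      expect_equal(poisson_upper_tail(k, lam), tail_oracle(k, lam),
                   tolerance = 1e-9)
    }
  }
  # strictly decreasing in the observed count
  p <- poisson_upper_tail(0:20, 5)
  expect_true(all(diff(p) < 0))
  expect_error(poisson_upper_tail(3, 0), "expected")
})

test_that("burden test flags excesses per type and pools units additively", {
  co <- demo_coeffs()
  e <- expected_counts(co, 30, 30)
  # observed equal to (rounded) expectation: nothing significant
  obs <- setNames(round(e$expected_total), e$type)
  bt <- burden_test(obs, e, unit = "child1")
  expect_s3_class(bt, "kin_burden")
  expect_false(any(bt$significant))
  expect_true(all(bt$p > 0 & bt$p <= 1))
  # push one type past its critical count: that type and only it fires
  lamCA <- e$expected_total[e$type == "C>A"]
  crit <- detection_threshold(lamCA)$critical_count
  obs2 <- obs; obs2["C>A"] <- crit
  bt2 <- burden_test(obs2, e, unit = "child2")
  expect_true(bt2$significant[bt2$type == "C>A"])
  expect_equal(bt2$enrichment[bt2$type == "C>A"], crit / lamCA)
  # family pooling: summed expectations equal element-wise sums
  e2 <- expected_counts(co, 25, 40)
  fam <- sum_expectations(e, e2)
  expect_equal(fam$expected_total, e$expected_total + e2$expected_total)
  # glance/tidy accessors
  g <- glance(bt2)
  expect_equal(g$n_significant_types, 1)
  expect_equal(nrow(tidy(bt2)), 7)
})

test_that("detection threshold is the smallest significant count", {
  bf_threshold <- function(lam, alpha = 0.05) {
    k <- 0
    while (tail_oracle(k, lam, upper = 1000) >= alpha) k <- k + 1
    k
  }
  for (lam in c(0.5, 1, 2, 5, 10)) {
    dt <- detection_threshold(lam)
    expect_equal(dt$critical_count, bf_threshold(lam))
    expect_equal(dt$extra, dt$critical_count - lam)
  }
  expect_equal(detection_threshold(1e-6)$critical_count, 1)
  # non-decreasing in the expectation
  cc <- vapply(seq(0.5, 20, by = 0.5),
               function(l) detection_threshold(l)$critical_count, integer(1))
  expect_true(all(diff(cc) >= 0))
})

test_that("parental fold elevation attributes the excess to the carrier", {
  expect_equal(parental_fold_elevation(6, 1, 3, "mother"), 3.0)
  expect_equal(parental_fold_elevation(6, 1, 3, "father"), 5 / 3)
  expect_equal(parental_fold_elevation(4, 1, 3, "mother"), 1.0)
  expect_warning(f <- parental_fold_elevation(2, 1, 3, "mother"), "below")
  expect_lt(f, 1)
  expect_error(parental_fold_elevation(5, 0, 3, "mother"), "> 0")
})

test_that("minimum detectable fold combines threshold and fold arithmetic", {
  # worked fixture: expected_mat 2, expected_pat 6, alpha 0.05
  lam <- 8
  k <- 0
  while (tail_oracle(k, lam, upper = 1000) >= 0.05) k <- k + 1
  mdf <- min_detectable_fold(2, 6, "mother")
  expect_equal(mdf$critical_count, k)
  expect_equal(mdf$fold, (2 + (k - 8)) / 2)
  # larger paternal share -> smaller paternal min-fold on the same totals
  mm <- min_detectable_fold(2, 6, "mother")$fold
  mp <- min_detectable_fold(2, 6, "father")$fold
  expect_lt(mp, mm)
  # symmetric when shares are equal
  expect_equal(min_detectable_fold(4, 4, "mother")$fold,
               min_detectable_fold(4, 4, "father")$fold)
})

test_that("spectrum_counts tallies passing calls by class", {
  calls <- tibble::tibble(
    spectrum_class = c("C>A", "C>A", "C>T", "A>G"),
    pass = c(TRUE, FALSE, TRUE, TRUE)
  )
  ct <- spectrum_counts(calls)
  expect_equal(ct[["C>A"]], 1)
  expect_equal(sum(ct), 3)
  expect_equal(sum(spectrum_counts(calls, pass_only = FALSE)), 4)
})
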