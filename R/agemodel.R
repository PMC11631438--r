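# Parental-age model: expected per-type DNM counts that are linear in
# parental age, exact one-tailed Poisson burden tests, detection thresholds,
# and parent-of-origin mutator effect sizes.

#' Build a parental-age coefficient table
#'
#' One row per 1-mer mutation class with maternal and paternal linear-model
#' coefficients: expected maternal count of type c is
#' `m_mat * a_mat + b_mat`, and likewise paternally. `reference_genome_bp`
#' records the (accessible) genome size the model was fit on, used to scale
#' expectations to a different accessible genome.
#'
#' @param coeffs Tibble with columns `type`, `m_mat`, `b_mat`, `m_pat`,
#'   `b_pat`; must contain each of [mutation_types()] exactly once.
#' @param reference_genome_bp Genome size the coefficients refer to.
#' @return A `kin_coeffs` tibble with a `reference_genome_bp` attribute.
#' @export
age_coefficients <- function(coeffs, reference_genome_bp) {
  x <- as_tibble(coeffs)
  stopifnot(all(c("type", "m_mat", "b_mat", "m_pat", "b_pat") %in% names(x)))
  if (!setequal(x$type, MUTATION_TYPES) || nrow(x) != 6) {
    abort("coefficients must contain each of the six mutation types exactly once")
  }
  stopifnot(reference_genome_bp > 0)
  x <- x[match(MUTATION_TYPES, x$type), ]
  attr(x, "reference_genome_bp") <- as.double(reference_genome_bp)
  class(x) <- c("kin_coeffs", class(x))
  x
}

#' Read / write a coefficient TSV
#'
#' On disk: a `#reference_genome_bp=<int>` header line followed by a TSV with
#' columns `type`, `m_mat`, `b_mat`, `m_pat`, `b_pat`.
#'
#' @param path File path.
#' @return A `kin_coeffs` (for the reader); `path` invisibly (writer).
#' @export
read_age_coefficients <- function(path) {
  first <- readLines(path, n = 1)
  m <- stringr::str_match(first, "^#\\s*reference_genome_bp\\s*=\\s*([0-9.eE+]+)")
  if (is.na(m[1, 2])) abort("coefficient TSV must start with '#reference_genome_bp=<bp>'")
  x <- readr::read_tsv(path, comment = "#", col_types = "cdddd")
  age_coefficients(x, as.double(m[1, 2]))
}

#' @rdname read_age_coefficients
#' @param coeffs A `kin_coeffs`.
#' @export
write_age_coefficients <- function(coeffs, path) {
  con <- file(path, "w")
  writeLines(paste0("#reference_genome_bp=",
                    format(attr(coeffs, "reference_genome_bp"),
                           scientific = FALSE)), con)
  close(con)
  readr::write_tsv(as_tibble(coeffs)[, c("type", "m_mat", "b_mat", "m_pat", "b_pat")],
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Expected per-type DNM counts for a child
#'
#' Evaluates the parental-age linear model at the parents' ages at conception
#' and scales by the fraction of the genome accessible for calling. Negative
#' model values (possible at very low ages with negative intercepts) are
#' floored at zero with a warning.
#'
#' @param coeffs A `kin_coeffs`.
#' @param a_mat,a_pat Maternal and paternal ages (years) at conception.
#' @param accessibility_scale Multiplicative accessibility correction in
#'   (0, 1]; typically `accessible_bp / reference_genome_bp`.
#' @return A `kin_expectation` tibble: `type`, `expected_mat`, `expected_pat`,
#'   `expected_total`, with ages and scale as attributes.
#' @export
expected_counts <- function(coeffs, a_mat, a_pat, accessibility_scale = 1) {
  stopifnot(inherits(coeffs, "kin_coeffs"), a_mat > 0, a_pat > 0,
            accessibility_scale > 0, accessibility_scale <= 1)
  em <- accessibility_scale * (coeffs$m_mat * a_mat + coeffs$b_mat)
  ep <- accessibility_scale * (coeffs$m_pat * a_pat + coeffs$b_pat)
  if (any(em < 0) || any(ep < 0)) {
    warn("expected_counts: negative model value(s) floored at 0")
    em <- pmax(em, 0)
    ep <- pmax(ep, 0)
  }
  out <- tibble(type = coeffs$type, expected_mat = em, expected_pat = ep,
                expected_total = em + ep)
  attr(out, "a_mat") <- a_mat
  attr(out, "a_pat") <- a_pat
  attr(out, "accessibility_scale") <- accessibility_scale
  class(out) <- c("kin_expectation", class(out))
  out
}

#' Sum expectations across children
#'
#' Family- and group-level burden tests pool children by summing observed and
#' expected counts element-wise per type (each child's expectation is scaled
#' by its own accessibility first).
#'
#' @param ... `kin_expectation` tibbles.
#' @return A pooled `kin_expectation`.
#' @export
sum_expectations <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !inherits(xs[[1]], "data.frame")) {
    xs <- xs[[1]]
  }
  stopifnot(length(xs) >= 1)
  out <- xs[[1]]
  for (x in xs[-1]) {
    stopifnot(identical(x$type, out$type))
    out$expected_mat <- out$expected_mat + x$expected_mat
    out$expected_pat <- out$expected_pat + x$expected_pat
    out$expected_total <- out$expected_total + x$expected_total
  }
  out
}

#' Exact upper-tail Poisson probability
#'
#' `P(X >= observed)` for `X ~ Poisson(expected)`; the exact tail, not a
#' normal approximation. Vectorised over `observed` and `expected`.
#'
#' @param observed Non-negative integer count(s).
#' @param expected Positive Poisson mean(s).
#' @return Upper-tail probabilities in (0, 1].
#' @export
poisson_upper_tail <- function(observed, expected) {
  if (any(expected <= 0)) abort("expected must be > 0")
  if (any(observed < 0)) abort("observed must be >= 0")
  ppois(observed - 1, expected, lower.tail = FALSE)
}

#' One-tailed Poisson burden test against the parental-age model
#'
#' Tests whether observed per-type DNM counts exceed the model's expected
#' counts, per type and in total; enrichment is observed/expected.
#' Significance is `p < alpha` one-tailed with no multiple-testing correction
#' by default (set `bonferroni = TRUE` to divide `alpha` by the number of
#' tests).
#'
#' @param observed Named numeric vector of observed counts per mutation type
#'   (names from [mutation_types()]), or a tibble with columns `type`, `observed`.
#' @param expectation A `kin_expectation` for the same unit.
#' @param unit Label for the tested unit (child, family or group id).
#' @param alpha One-tailed significance level.
#' @param bonferroni Apply a Bonferroni correction across the seven tests?
#' @return A `kin_burden` tibble: one row per type plus a `"total"` row, with
#'   `observed`, `expected`, `p`, `enrichment`, `significant`.
#' @export
burden_test <- function(observed, expectation, unit = "unit",
                        alpha = 0.05, bonferroni = FALSE) {
  stopifnot(inherits(expectation, "kin_expectation"))
  if (is.data.frame(observed)) {
    observed <- setNames(observed$observed, observed$type)
  }
  if (!all(MUTATION_TYPES %in% names(observed))) {
    abort("observed must carry counts for all six mutation types")
  }
  obs <- observed[MUTATION_TYPES]
  exp_t <- setNames(expectation$expected_total, expectation$type)[MUTATION_TYPES]
  obs_all <- c(obs, total = sum(obs))
  exp_all <- c(exp_t, total = sum(exp_t))
  thr <- if (bonferroni) alpha / length(obs_all) else alpha
  p <- poisson_upper_tail(obs_all, exp_all)
  out <- tibble(
    unit = unit,
    type = names(obs_all),
    observed = as.double(obs_all),
    expected = as.double(exp_all),
    p = p,
    enrichment = as.double(obs_all) / as.double(exp_all),
    significant = p < thr
  )
  attr(out, "alpha") <- alpha
  attr(out, "bonferroni") <- bonferroni
  class(out) <- c("kin_burden", class(out))
  out
}

#' Smallest significant count under a Poisson expectation
#'
#' The detection threshold: the minimum integer count whose exact upper-tail
#' probability falls below `alpha`, and the implied number of mutations in
#' excess of the expectation.
#'
#' @param expected Positive Poisson mean.
#' @param alpha One-tailed significance level.
#' @return A list: `critical_count` (integer) and `extra`
#'   (`critical_count - expected`).
#' @export
detection_threshold <- function(expected, alpha = 0.05) {
  stopifnot(expected > 0, alpha > 0, alpha < 1)
  cc <- qpois(1 - alpha, expected)
  # qpois gives smallest q with P(X <= q) >= 1 - alpha; want smallest c with
  # P(X >= c) < alpha, i.e. P(X <= c - 1) > 1 - alpha (strict)
  while (poisson_upper_tail(cc, expected) >= alpha) cc <- cc + 1
  while (cc > 0 && poisson_upper_tail(cc - 1, expected) < alpha) cc <- cc - 1
  list(critical_count = as.integer(cc), extra = cc - expected)
}

#' Fold elevation of the carrier parent's mutation rate
#'
#' Attributes the entire excess of observed over expected counts to the
#' carrier parent's germline: `excess = observed - (expected_mat +
#' expected_pat)`, and the fold elevation is
#' `(expected_carrier + excess) / expected_carrier`. Values below 1 (negative
#' excess) are reported as-is with a warning.
#'
#' @param observed_total Observed count (for the tested type).
#' @param expected_mat,expected_pat Expected maternal and paternal counts.
#' @param carrier `"mother"` or `"father"`: which parent carries the
#'   candidate mutator genotype.
#' @return The fold elevation (numeric).
#' @export
parental_fold_elevation <- function(observed_total, expected_mat, expected_pat,
                                    carrier = c("mother", "father")) {
  carrier <- match.arg(carrier)
  exp_carrier <- if (carrier == "mother") expected_mat else expected_pat
  if (exp_carrier <= 0) abort("carrier parent's expected count must be > 0")
  excess <- observed_total - (expected_mat + expected_pat)
  if (excess < 0) warn("parental_fold_elevation: observed below expectation; fold < 1")
  (exp_carrier + excess) / exp_carrier
}

#' Minimum detectable fold elevation for a carrier parent
#'
#' Combines [detection_threshold()] on the unit's total expectation for one
#' mutation type with [parental_fold_elevation()] at the critical count: the
#' smallest carrier-parent rate inflation that would produce a significant
#' one-tailed Poisson deviation.
#'
#' @param expected_mat,expected_pat Expected maternal and paternal counts for
#'   the type of interest (typically C>A).
#' @param carrier `"mother"` or `"father"`.
#' @param alpha One-tailed significance level.
#' @return A list: `critical_count`, `extra`, `fold`.
#' @export
min_detectable_fold <- function(expected_mat, expected_pat,
                                carrier = c("mother", "father"), alpha = 0.05) {
  carrier <- match.arg(carrier)
  stopifnot(expected_mat > 0, expected_pat > 0)
  dt <- detection_threshold(expected_mat + expected_pat, alpha)
  fold <- suppressWarnings(parental_fold_elevation(
    dt$critical_count, expected_mat, expected_pat, carrier
  ))
  c(dt, list(fold = fold))
}

#' Tally passing calls by 1-mer class
#'
#' @param calls A `kin_calls` tibble.
#' @param pass_only Count only passing calls?
#' @return Named numeric vector over [mutation_types()].
#' @export
spectrum_counts <- function(calls, pass_only = TRUE) {
  x <- if (pass_only) calls[calls$pass %in% TRUE, ] else calls
  counts <- table(factor(x$spectrum_class, levels = MUTATION_TYPES))
  setNames(as.double(counts), MUTATION_TYPES)
}
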