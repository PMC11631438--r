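# Generation-time regression for recombinant inbred mouse strains, and the
# cellular repair-assay function score.

#' Read a BXD strain summary CSV
#'
#' Expected columns: `strain`, `genotype` (`"B"` or `"D"` at the Mutyh
#' locus), `n_generations`, `n_years`, `ca_count`, `accessible_bp`. Derives
#' `generation_time = n_years / n_generations` (years) and
#' `ca_rate = ca_count / n_generations / accessible_bp` (C>A mutations per
#' site per generation).
#'
#' @param path CSV path.
#' @return A tibble of strain records with derived columns.
#' @export
read_bxd <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    strain = "c", genotype = "c", n_generations = "d", n_years = "d",
    ca_count = "d", accessible_bp = "d"
  ))
  bxd_records(x)
}

#' @rdname read_bxd
#' @param x Tibble with the raw columns (see above).
#' @export
bxd_records <- function(x) {
  x <- as_tibble(x)
  stopifnot(all(c("strain", "genotype", "n_generations", "n_years",
                  "ca_count", "accessible_bp") %in% names(x)))
  if (!all(x$genotype %in% c("B", "D"))) abort("genotype must be 'B' or 'D'")
  if (any(x$n_generations <= 0)) abort("n_generations must be > 0")
  x$generation_time <- x$n_years / x$n_generations
  x$ca_rate <- x$ca_count / x$n_generations / x$accessible_bp
  x
}

#' Regress the C>A mutation rate on generation time and Mutyh genotype
#'
#' Ordinary least squares of the per-generation, per-site C>A mutation rate
#' on generation time (centred at the minimum observed generation time, so
#' intercepts are rates at that minimum age) plus the categorical Mutyh
#' genotype. A model with a genotype-by-generation-time interaction is fitted
#' separately to test slope homogeneity between the B and D strains.
#'
#' @param records Strain tibble from [read_bxd()] / [bxd_records()].
#' @param min_generation_time Centring value in years; defaults to the
#'   minimum observed generation time.
#' @return A `kin_bxd` list: `slope` (rate/site/year), `intercept_B`,
#'   `intercept_D` (rate/site/generation at the minimum generation time),
#'   `p_slope`, `p_genotype`, `p_interaction`, `min_generation_time`,
#'   `fit` and `fit_interaction` (the underlying `lm` objects).
#' @export
bxd_regression <- function(records, min_generation_time = NULL) {
  stopifnot(all(c("generation_time", "ca_rate", "genotype") %in% names(records)))
  tab <- table(records$genotype)
  if (length(tab) < 2) abort("records must include both B and D genotypes")
  if (any(tab < 3)) abort("need at least 3 records per genotype class")
  m0 <- min_generation_time %||% min(records$generation_time)
  d <- records
  d$gt_centered <- d$generation_time - m0
  d$genotype <- factor(d$genotype, levels = c("B", "D"))
  fit <- lm(ca_rate ~ gt_centered + genotype, data = d)
  if (fit$rank < 3) abort("rank-deficient design")
  fit_int <- lm(ca_rate ~ gt_centered * genotype, data = d)
  cf <- coef(fit)
  sm <- summary(fit)$coefficients
  p_int <- anova(fit, fit_int)[["Pr(>F)"]][2]
  structure(
    list(
      slope = unname(cf["gt_centered"]),
      intercept_B = unname(cf["(Intercept)"]),
      intercept_D = unname(cf["(Intercept)"] + cf["genotypeD"]),
      p_slope = unname(sm["gt_centered", "Pr(>|t|)"]),
      p_genotype = unname(sm["genotypeD", "Pr(>|t|)"]),
      p_interaction = p_int,
      min_generation_time = m0,
      fit = fit, fit_interaction = fit_int
    ),
    class = "kin_bxd"
  )
}

#' @export
print.kin_bxd <- function(x, ...) {
  cat("<kin_bxd> C>A rate ~ (generation time - ",
      signif(x$min_generation_time, 3), " yr) + Mutyh genotype\n", sep = "")
  cat(sprintf("  slope       %.3g per site per year (p = %.2g)\n",
              x$slope, x$p_slope))
  cat(sprintf("  intercept B %.3g per site per generation\n", x$intercept_B))
  cat(sprintf("  intercept D %.3g per site per generation (p = %.2g)\n",
              x$intercept_D, x$p_genotype))
  cat(sprintf("  slope x genotype interaction: p = %.2g\n", x$p_interaction))
  invisible(x)
}

#' Repair-assay function score
#'
#' `log2` ratio of a variant's fraction of repair-positive transfected cells
#' to the wild-type fraction: 0 means wild-type-like repair, negative scores
#' mean deficient function. A zero variant fraction is replaced by
#' `pseudocount` before taking the ratio.
#'
#' @param repair_pos_fraction_variant Variant's repair-positive fraction in
#'   \[0, 1\].
#' @param repair_pos_fraction_wt Wild-type repair-positive fraction in (0, 1].
#' @param pseudocount Replacement for a zero variant fraction.
#' @return The function score (numeric, vectorised).
#' @export
function_score <- function(repair_pos_fraction_variant, repair_pos_fraction_wt,
                           pseudocount = 1e-3) {
  if (any(repair_pos_fraction_wt <= 0)) abort("wild-type fraction must be > 0")
  v <- ifelse(repair_pos_fraction_variant == 0, pseudocount,
              repair_pos_fraction_variant)
  log2(v / repair_pos_fraction_wt)
}
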