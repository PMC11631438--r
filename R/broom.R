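# broom-style accessors for fitted/result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a burden-test result
#'
#' @param x A `kin_burden`.
#' @param ... Unused.
#' @return The per-type rows (plus total) as a plain tibble.
#' @export
tidy.kin_burden <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' One-row summary of a burden-test result
#'
#' @param x A `kin_burden`.
#' @param ... Unused.
#' @return Tibble with unit, total observed/expected, total-burden p and
#'   enrichment, and the number of significant mutation types.
#' @export
glance.kin_burden <- function(x, ...) {
  tot <- x[x$type == "total", ]
  tibble(
    unit = tot$unit,
    observed_total = tot$observed,
    expected_total = tot$expected,
    p_total = tot$p,
    enrichment_total = tot$enrichment,
    n_significant_types = sum(x$significant[x$type != "total"]),
    alpha = attr(x, "alpha")
  )
}

#' Tidy a BXD generation-time regression
#'
#' @param x A `kin_bxd`.
#' @param ... Unused.
#' @return Tibble of the quantities of interest: slope per year, per-genotype
#'   intercepts at the minimum generation time, and their p-values.
#' @export
tidy.kin_bxd <- function(x, ...) {
  tibble(
    term = c("slope_per_year", "intercept_B", "intercept_D"),
    estimate = c(x$slope, x$intercept_B, x$intercept_D),
    p.value = c(x$p_slope, NA_real_, x$p_genotype)
  )
}

#' One-row summary of a BXD regression
#'
#' @param x A `kin_bxd`.
#' @param ... Unused.
#' @return Tibble with fit statistics and the interaction test p-value.
#' @export
glance.kin_bxd <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    p_interaction = x$p_interaction,
    min_generation_time = x$min_generation_time,
    nobs = length(x$fit$residuals)
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
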