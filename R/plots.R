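# ggplot2 views of the main result types.

#' Plot callable fraction against number of surrogate siblings
#'
#' Theoretical curves (1 - 2^-n with one real parent, (1 - 2^-n)^2 with
#' none) with optional empirical points overlaid.
#'
#' @param n_max Largest surrogate count to draw.
#' @param empirical Optional tibble with columns `n_surrogate_sibs`,
#'   `n_real_parents`, `callable_fraction`.
#' @return A ggplot object.
#' @export
plot_callable_fraction <- function(n_max = 4, empirical = NULL) {
  theory <- tidyr::expand_grid(
    n_surrogate_sibs = 0:n_max,
    n_real_parents = c(0L, 1L)
  ) |>
    mutate(
      callable_fraction = theoretical_callable_fraction(
        .data$n_surrogate_sibs, .data$n_real_parents),
      configuration = if_else(.data$n_real_parents == 1L,
                              "one real parent", "no real parents")
    )
  p <- ggplot2::ggplot(theory, ggplot2::aes(
    x = .data$n_surrogate_sibs, y = .data$callable_fraction,
    colour = .data$configuration
  )) +
    ggplot2::geom_line(linetype = "dashed") +
    ggplot2::geom_point(shape = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "surrogate siblings", y = "callable fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(empirical)) {
    emp <- mutate(empirical, configuration = if_else(
      .data$n_real_parents == 1L, "one real parent", "no real parents"))
    p <- p + ggplot2::geom_point(data = emp, size = 2)
  }
  p
}

#' Plot observed vs expected burden per mutation type
#'
#' @param object A `kin_burden`.
#' @param ... Unused.
#' @return A ggplot object with observed and expected counts per 1-mer type;
#'   significant types are highlighted.
#' @export
autoplot.kin_burden <- function(object, ...) {
  d <- as_tibble(object) |> filter(.data$type != "total")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$type), vjust = -0.8, size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
    ggplot2::labs(x = "expected count (parental-age model)",
                  y = "observed count",
                  colour = "p < alpha") +
    ggplot2::theme_minimal()
}

#' Histogram of call VAFs with the germline expectation marked
#'
#' @param calls A `kin_calls` tibble.
#' @param flag_threshold Median-VAF screening threshold to annotate.
#' @return A ggplot object.
#' @export
plot_vaf <- function(calls, flag_threshold = 0.40) {
  d <- filter(as_tibble(calls), !is.na(.data$vaf))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$vaf)) +
    ggplot2::geom_histogram(binwidth = 0.02, boundary = 0) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = flag_threshold, colour = "red",
                        linetype = "dotted") +
    ggplot2::labs(x = "variant allele fraction", y = "calls") +
    ggplot2::theme_minimal()
}

#' Plot the BXD generation-time regression
#'
#' @param object A `kin_bxd` fit.
#' @param records The strain records used in the fit.
#' @param ... Unused.
#' @return A ggplot object: per-strain C>A rates against generation time,
#'   with the fitted genotype-specific lines.
#' @export
autoplot.kin_bxd <- function(object, records, ...) {
  d <- records
  d$fitted <- object$intercept_B + object$slope *
    (d$generation_time - object$min_generation_time) +
    (d$genotype == "D") * (object$intercept_D - object$intercept_B)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$generation_time,
                                  y = .data$ca_rate,
                                  colour = .data$genotype)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted)) +
    ggplot2::labs(x = "generation time (years)",
                  y = "C>A mutations / site / generation",
                  colour = "Mutyh") +
    ggplot2::theme_minimal()
}
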