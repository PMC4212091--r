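#' Plot a bias catalog
#'
#' Histogram of the per-variant reference-allele ratio in correctly mapped
#' simulated reads, faceted by variant class — unbiased variants pile up at
#' 0.5, reference-favored loci push toward 1.
#'
#' @param object An `mb_bias_catalog`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mb_bias_catalog <- function(object, ...) {
  d <- object$variants |> filter(!is.na(.data$ref_ratio))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ref_ratio,
                                  fill = .data$flagged)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::facet_wrap(~vclass, scales = "free_y") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "reference allele ratio in mapped simulated reads",
                  y = "variants", fill = "biased") +
    ggplot2::theme_minimal()
}

#' Compare two bias catalogs variant-by-variant
#'
#' Scatter of reference-allele ratios over shared variants (one panel per
#' variant class), with the `bias_threshold` concordance band.
#'
#' @param cat_a,cat_b `mb_bias_catalog`s or variant bias tables.
#' @param threshold Band half-width (default 0.05).
#' @return A ggplot.
#' @export
plot_catalog_comparison <- function(cat_a, cat_b, threshold = 0.05) {
  va <- if (inherits(cat_a, "mb_bias_catalog")) cat_a$variants else cat_a
  vb <- if (inherits(cat_b, "mb_bias_catalog")) cat_b$variants else cat_b
  d <- inner_join(va, vb, by = "variant_id", suffix = c("_a", "_b")) |>
    filter(!is.na(.data$ref_ratio_a), !is.na(.data$ref_ratio_b))
  ggplot2::ggplot(d, ggplot2::aes(.data$ref_ratio_a, .data$ref_ratio_b)) +
    ggplot2::geom_abline(slope = 1, intercept = c(-threshold, 0, threshold),
                         linetype = c(3, 2, 3)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~vclass_a) +
    ggplot2::labs(x = "reference allele ratio (catalog A)",
                  y = "reference allele ratio (catalog B)") +
    ggplot2::theme_minimal()
}

#' Plot before/after eQTL P values
#'
#' The classic filtering diagnostic: per-gene -log10 nominal P before vs after
#' removing reads at biased start sites, colored by change class. Bias-driven
#' false positives fall far below the diagonal.
#'
#' @param object An `mb_eqtl_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mb_eqtl_comparison <- function(object, ...) {
  d <- object$genes
  ggplot2::ggplot(d, ggplot2::aes(-log10(.data$p_nominal_before),
                                  -log10(.data$p_nominal_after),
                                  color = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "-log10 P (unfiltered)", y = "-log10 P (filtered)",
                  color = "eQTL class") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
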