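# ggplot2 displays for the main result types.

#' Strip plot of heritability estimates by lipid class
#'
#' Per-lipid h2 estimates grouped by class, significant lipids emphasized;
#' the standard display for a lipidome-wide heritability screen.
#'
#' @param fits Heritability tibble with `lipid`, `h2`, `p_h2` (e.g. from
#'   [fit_lipidome_heritability()]).
#' @param alpha Significance level for the emphasis, default 0.05.
#' @return A ggplot object.
#' @export
plot_heritability_by_class <- function(fits, alpha = 0.05) {
  df <- dplyr::mutate(tibble::as_tibble(fits),
                      lipid_class = parse_lipid_name(.data$lipid)$lipid_class,
                      significant = .data$p_h2 < alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lipid_class, y = .data$h2)) +
    ggplot2::geom_boxplot(outlier.shape = NA, colour = "grey55") +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$significant),
                         width = 0.15, height = 0, size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "grey70"),
                                 name = "significantly heritable") +
    ggplot2::labs(x = "lipid class", y = expression(h^2)) +
    ggplot2::theme_minimal()
}

#' Heritability vs variance explained by gene expression
#'
#' Scatter of per-lipid h2 against the pseudo-r2 of the selected expression
#' probes.
#'
#' @param fits Heritability tibble with `lipid`, `h2`.
#' @param varexp Tibble with `lipid` and `nagelkerke` (or `mcfadden`).
#' @param r2 Which pseudo-r2 column to plot, default `"nagelkerke"`.
#' @return A ggplot object.
#' @export
plot_h2_vs_varexp <- function(fits, varexp, r2 = "nagelkerke") {
  df <- dplyr::inner_join(tibble::as_tibble(fits), tibble::as_tibble(varexp),
                          by = "lipid")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[r2]], y = .data$h2)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.5) +
    ggplot2::labs(x = paste0("variance explained (", r2, " r²)"),
                  y = expression(h^2)) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_gxe_age Plot h2 as a function of age.
#' @param object A `twin_gxe_fit`.
#' @param ... Unused.
#' @export
autoplot.twin_gxe_fit <- function(object, ...) {
  ggplot2::ggplot(object$h2_by_age, ggplot2::aes(x = .data$age, y = .data$h2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "age (years)", y = expression(h^2(age))) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
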