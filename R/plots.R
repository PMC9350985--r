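#' Heatmaps of a deviation landscape
#'
#' One tile per null-space node, faceted by index. `what = "delta"` shows
#' the raw beta-deviation (diverging palette centred at 0), `"p_value"` the
#' significance landscape, `"significance"` the two-tailed mask.
#'
#' @param object A [beta_landscape()] (possibly carrying a `stage` column,
#'   in which case facets are index x stage).
#' @param what One of `"delta"`, `"p_value"`, `"significance"`.
#' @param alpha Significance level for the mask.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.beta_landscape <- function(object, what = c("delta", "p_value",
                                                     "significance"),
                                    alpha = 0.05, ...) {
  what <- match.arg(what)
  tb <- tibble::as_tibble(object)
  tb$fill_val <- switch(what,
    delta = tb$delta,
    p_value = tb$p_value,
    significance = tb$p_value < alpha | tb$p_value > 1 - alpha
  )
  p <- ggplot2::ggplot(tb, ggplot2::aes(
    x = .data$d_col_target, y = .data$d_row_target, fill = .data$fill_val
  )) +
    ggplot2::geom_tile() +
    ggplot2::labs(
      x = "column (taxon frequency) discrepancy",
      y = "row (site richness) discrepancy",
      fill = switch(what, delta = "Δβ", p_value = "p",
                    significance = "significant")
    ) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
  p <- p + if ("stage" %in% names(tb)) {
    ggplot2::facet_grid(stage ~ index)
  } else {
    ggplot2::facet_wrap(~index)
  }
  if (what == "delta") {
    p <- p + ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                           high = "#b2182b", midpoint = 0)
  } else if (what == "p_value") {
    p <- p + ggplot2::scale_fill_viridis_c(limits = c(0, 1))
  }
  p
}

#' @export
plot.beta_landscape <- function(x, ...) print(autoplot.beta_landscape(x, ...))

#' Boxplots of per-node deviations by stage
#'
#' Distribution of per-node beta-deviations within a conservativeness
#' quarter, by stage and index: the graphical counterpart of the Wilcoxon
#' stage comparisons.
#'
#' @param object A [run_study()] result.
#' @param level Conservativeness level to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.study_result <- function(object, level = c("moderate", "conservative",
                                                    "liberal"), ...) {
  level <- match.arg(level)
  tb <- conservativeness_subset(object$landscape, level)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$stage, y = .data$delta,
                                   fill = .data$stage)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Δβ",
                  title = paste0(level, " null models")) +
    ggplot2::theme_minimal()
}

#' @export
plot.study_result <- function(x, ...) print(autoplot.study_result(x, ...))
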