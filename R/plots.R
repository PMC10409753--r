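#' Genotype heatmap of a call matrix
#'
#' Sites as rows, cells as columns, coloured by call: reference blue,
#' heterozygous yellow, alternate red, dropout white — the standard view for
#' judging how smoothing fills in a sparse genotype matrix.
#'
#' @param calls Genotype call matrix (R/H/A/MISSING).
#' @param cell_order Optional ordering of the columns (e.g. by clade).
#' @return A ggplot object.
#' @export
plot_genotype_heatmap <- function(calls, cell_order = colnames(calls)) {
  tab <- tibble::tibble(
    site = factor(rep(rownames(calls), times = ncol(calls)),
                  levels = rev(rownames(calls))),
    cell = factor(rep(colnames(calls), each = nrow(calls)),
                  levels = cell_order),
    call = factor(as.vector(calls), levels = c("R", "H", "A", "MISSING"))
  )
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$cell, y = .data$site,
                                    fill = .data$call)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(R = "#2166AC", H = "#FFD92F",
                                          A = "#B2182B",
                                          MISSING = "white"),
                               drop = FALSE, name = "Genotype") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank()) +
    ggplot2::labs(x = "cells", y = "sites")
}

#' Plot a robustness sweep
#'
#' @param object A results tibble from [run_robustness_sweep()].
#' @param metric Column to plot (default `"lambda"`).
#' @param ... Unused.
#' @return A ggplot bar chart of the metric across the swept parameter.
#' @export
autoplot.cellphylo_sweep <- function(object, metric = "lambda", ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$value),
                                       y = .data[[metric]])) +
    ggplot2::geom_col(fill = "#4C72B0") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = unique(object$sweep), y = metric)
}

#' @rdname autoplot.cellphylo_sweep
#' @param sweep_results A sweep results tibble.
#' @export
plot_sweep <- function(sweep_results, metric = "lambda") {
  class(sweep_results) <- c("cellphylo_sweep", class(sweep_results))
  autoplot(sweep_results, metric = metric)
}
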