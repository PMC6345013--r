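# ggplot2 visualizations for scan, screen and connectivity results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a robustness scan
#'
#' @param object A tibble from [robustness_scan()].
#' @param ... Unused.
#' @return A ggplot: objective optimum against the controlled flux.
#' @export
autoplot.stilflux_scan <- function(object, ...) {
  rxn <- attr(object, "reaction")
  xlab <- if (isTRUE(attr(object, "uptake"))) {
    paste0(rxn, " uptake rate (mmol/gDW/h)")
  } else {
    paste0(rxn, " flux (mmol/gDW/h)")
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value,
                                       y = .data$objective_value)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$status), size = 2) +
    ggplot2::labs(x = xlab, y = "optimal objective (mmol/gDW/h)",
                  shape = "solver status") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.stilflux_scan
#' @param scan A tibble from [robustness_scan()].
#' @export
plot_robustness <- function(scan, ...) autoplot.stilflux_scan(scan, ...)

#' Plot a single-gene deletion screen
#'
#' @param object A tibble from [single_gene_deletion()].
#' @param ... Unused.
#' @return A ggplot: knockout/wild-type growth ratio per gene, essential
#'   genes highlighted.
#' @export
autoplot.stilflux_deletions <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$ratio)
  df$gene <- factor(df$gene, levels = df$gene)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$ratio,
                                   fill = .data$essential)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey65",
                                          `TRUE` = "#d95f02")) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "knockout growth / wild-type growth",
                  fill = "essential") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.stilflux_deletions
#' @param screen A tibble from [single_gene_deletion()].
#' @export
plot_deletions <- function(screen, ...) autoplot.stilflux_deletions(screen, ...)

#' Plot metabolite connectivity
#'
#' @param object A tibble from [metabolite_connectivity()].
#' @param top Number of top-ranked metabolites shown.
#' @param ... Unused.
#' @return A ggplot ranking metabolites by reaction count.
#' @export
autoplot.stilflux_connectivity <- function(object, top = 18, ...) {
  df <- utils::head(tibble::as_tibble(object), top)
  df$metabolite <- factor(df$metabolite, levels = rev(df$metabolite))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metabolite, y = .data$count)) +
    ggplot2::geom_col(fill = "#74a9cf") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "reactions involving the metabolite") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.stilflux_connectivity
#' @param connectivity A tibble from [metabolite_connectivity()].
#' @export
plot_connectivity <- function(connectivity, top = 18, ...) {
  autoplot.stilflux_connectivity(connectivity, top = top, ...)
}
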