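# ggplot2 views of the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a tagged gene-by-condition matrix
#'
#' @param object A `gexpo_matrix` (merged ratios, counts, relative values or
#'   virtual two-color columns).
#' @param ... Unused.
#' @return A ggplot: genes by conditions, fill = cell value, missing cells
#'   blank.
#' @export
#' @method autoplot gexpo_matrix
autoplot.gexpo_matrix <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"gene_id",
                              names_to = "condition", values_to = "value")
  long$condition <- factor(long$condition, levels = names(object)[-1L])
  long$gene_id <- factor(long$gene_id, levels = rev(object$gene_id))
  tag <- concept_tag(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$gene_id,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "condition", y = "gene",
                  fill = if (is.na(tag)) "value" else tag) +
    ggplot2::theme_minimal()
}

#' Record-flow chart of a run report
#'
#' @param object A `gexpo_run_report`.
#' @param ... Unused.
#' @return A ggplot: records in/out and per-reason drops, one facet per
#'   connector for composite runs.
#' @export
#' @method autoplot gexpo_run_report
autoplot.gexpo_run_report <- function(object, ...) {
  t <- tidy(object)
  ggplot2::ggplot(t, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$connector), scales = "free_x") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "records") +
    ggplot2::theme_minimal()
}

#' Bar chart of KEGG regulation colors
#'
#' @param entries Color entries from [c2_run()] (columns `gene_id`,
#'   `color`).
#' @return A ggplot with one bar per regulation color, filled in the KEGG
#'   Mapper scheme (red = up, green = down, yellow = undefined).
#' @export
plot_regulation_colors <- function(entries) {
  counts <- dplyr::count(entries, .data$color)
  counts$color <- factor(counts$color, levels = c("red", "yellow", "green"))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$color, y = .data$n,
                                       fill = .data$color)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(red = "#cc3333", green = "#339933",
                                          yellow = "#e6b800")) +
    ggplot2::labs(x = "regulation color", y = "genes") +
    ggplot2::theme_minimal()
}
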