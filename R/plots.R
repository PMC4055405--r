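# Summary figures: category bars for a cohort summary, copy-number box
# plots for a Ping-group panel, and the lineage timeline.

#' @export
autoplot.cohort_summary <- function(object, ...) {
  dat <- object$by_category
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$category, -.data$n),
                                    y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "de novo insertions",
                  title = sprintf("%d de novo insertions", object$total)) +
    ggplot2::theme_minimal()
}

#' Box plot of mPing copy numbers by Ping group
#'
#' @param panel Panel tibble as from [generate_ag_panel()] (columns `group`
#'   and `mping_copies`).
#' @return A ggplot.
#' @export
plot_copy_numbers <- function(panel) {
  lv <- intersect(c("no-Ping", "C-type", "T-type"), unique(panel$group))
  ggplot2::ggplot(panel,
                  ggplot2::aes(x = factor(.data$group, levels = lv),
                               y = .data$mping_copies)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::labs(x = NULL, y = "mPing copy number") +
    ggplot2::theme_minimal()
}

#' Timeline plot of a lineage tree
#'
#' Draws each compartment as a horizontal segment over its existence
#' interval, with split points marked.
#'
#' @param tree A `lineage_tree`.
#' @return A ggplot.
#' @export
plot_lineage <- function(tree) {
  nodes <- tree$nodes |>
    mutate(tissue_lab = map_chr(.data$tissue, function(t) {
      if (length(t)) paste(t, collapse = "+") else ""
    }),
    label = ifelse(nzchar(.data$tissue_lab),
                   paste0(.data$name, " (", .data$tissue_lab, ")"), .data$name))
  nodes$y <- stats::reorder(nodes$label, nodes$birth)
  ggplot2::ggplot(nodes) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$birth, xend = .data$end,
                                       y = .data$y, yend = .data$y),
                          linewidth = 1.2) +
    ggplot2::geom_point(ggplot2::aes(x = .data$birth, y = .data$y), size = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "days after pollination", y = NULL) +
    ggplot2::theme_minimal()
}
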