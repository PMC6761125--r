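#' @title Plots
#'
#' @description ggplot2 graphics for the main result types: metagene profiles
#' with their confidence band, pausing-index distributions per expression
#' group, and per-gene TES-shift distributions per gene group. Boxplot
#' outliers are hidden from shift plots (but retained in all statistics).
#'
#' @name plots
NULL

#' Plot a metagene profile
#'
#' Mean signal (line) with the confidence band (ribbon). Gene-body profiles
#' are faceted by segment.
#'
#' @param object a `metagene_profile`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$offset, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = if (identical(attr(object, "anchor"), "gene_body"))
        "position (bp in flanks, % bins in body)"
      else paste0("distance from ", attr(object, "anchor"), " (bp)"),
      y = "mean coverage",
      title = sprintf("%s-anchored metagene (%d genes)",
                      attr(object, "anchor"), attr(object, "n_genes"))
    ) +
    ggplot2::theme_minimal()
  if ("segment" %in% names(object)) {
    p <- p + ggplot2::facet_grid(
      cols = ggplot2::vars(factor(.data$segment,
                                  c("upstream", "body", "downstream"))),
      scales = "free_x", space = "free_x"
    )
  }
  p
}

#' Boxplots of log2 pausing indexes per expression group and condition
#'
#' @param records one or more [pausing_index()] outputs bound together.
#' @param groups tibble `gene_id`, `expression_group`.
#' @return a ggplot.
#' @export
plot_pausing_index <- function(records, groups) {
  df <- records |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::inner_join(groups, by = "gene_id")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$expression_group),
                                   y = .data$log2_pi,
                                   fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$antibody)) +
    ggplot2::labs(x = "expression group (low to high)",
                  y = "log2 (3' pausing index)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Boxplots of per-gene TES shifts per gene group
#'
#' Points outside the whiskers are not drawn; all values still enter the
#' statistics.
#'
#' @param shifts [per_gene_shifts()] output.
#' @param groups tibble `gene_id`, `group`.
#' @return a ggplot.
#' @export
plot_shift_distribution <- function(shifts, groups) {
  df <- dplyr::inner_join(shifts, groups, by = "gene_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$shift)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "TES shift (bp, downstream positive)") +
    ggplot2::theme_minimal()
}

#' @export
tidy.metagene_profile <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
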