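#' Violin plot of likelihood proportions
#'
#' Displays where the best and constraint trees sit relative to the
#' suboptimal-tree likelihood cloud, per gene: the constraint tree of a
#' well-supported HGT falls outside (or on the tail of) the suboptimal
#' distribution.
#'
#' @param proportions tibble from [likelihood_proportions()], optionally
#'   with a `gene` column when several genes are combined.
#' @return a ggplot object.
#' @export
plot_likelihood_proportions <- function(proportions) {
  if (!"gene" %in% names(proportions)) proportions$gene <- "gene"
  sub <- dplyr::filter(proportions, .data$type == "suboptimal")
  pts <- dplyr::filter(proportions, .data$type != "suboptimal")
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$gene,
                                    y = .data$proportion)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey55") +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(colour = .data$type), size = 2.5) +
    ggplot2::scale_colour_manual(
      values = c(best = "#c0392b", constrained = "#2471a3"),
      name = NULL) +
    ggplot2::labs(x = NULL, y = "likelihood proportion") +
    ggplot2::theme_minimal()
}

#' Expression profile plot for selected genes
#'
#' Per-time-point replicate medians of normalized expression over the
#' developmental timecourse, one panel per gene.
#'
#' @param mat a normalized `expression_matrix`.
#' @param genes genes to show.
#' @return a ggplot object.
#' @export
plot_expression_profiles <- function(mat, genes) {
  stopifnot(inherits(mat, "expression_matrix"))
  long <- tidy.expression_matrix(mat)
  long <- dplyr::filter(long, .data$gene %in% genes)
  med <- long |>
    dplyr::group_by(.data$gene, .data$hours) |>
    dplyr::summarise(value = median(.data$value), .groups = "drop")
  ggplot2::ggplot(med, ggplot2::aes(x = .data$hours, y = .data$value)) +
    ggplot2::geom_line(colour = "#2471a3") +
    ggplot2::geom_point(data = long,
                        ggplot2::aes(y = .data$value),
                        alpha = 0.35, size = 0.8) +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = "hours post fertilization",
                  y = "tags per million (replicate points, median line)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plot_likelihood_proportions
#' @param object an `hgt_report` with phylogenetic test details.
#' @param ... unused.
#' @method autoplot hgt_report
#' @export
autoplot.hgt_report <- function(object, ...) {
  if (is.null(object$details$proportions))
    stop("report has no likelihood proportions (no phylogenetic test ran)")
  pr <- object$details$proportions
  pr$gene <- object$summary$gene
  plot_likelihood_proportions(pr)
}
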