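# ggplot2 views of the main result types.

#' Plot per-sample depurination estimates
#'
#' Adenine fraction with 95% Wilson intervals; QC-failed replicates are
#' hollow. If a `group` column is present samples are coloured by group.
#'
#' @param object an `srl_estimates` tibble from [estimate_depurination()]
#' @param ... unused
#' @return a ggplot
#' @method autoplot srl_estimates
#' @export
autoplot.srl_estimates <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$adenine_fraction))
  if ("group" %in% names(df)) {
    p <- p + ggplot2::aes(colour = .data$group)
  }
  p +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high,
                                          shape = .data$passed_qc)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "passed QC") +
    ggplot2::scale_y_continuous(limits = c(NA, 1)) +
    ggplot2::labs(x = NULL, y = "adenine fraction at SRL target",
                  title = "Depurination at the sarcin-ricin loop") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot Venn region counts per direction
#'
#' @param object a [venn_partition()] result
#' @param ... unused
#' @return a ggplot of gene counts per region, faceted by direction
#' @method autoplot venn_partition
#' @export
autoplot.venn_partition <- function(object, ...) {
  venn_counts(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$region, y = .data$n_genes)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~direction, ncol = 1) +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Direction-stratified Venn regions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot power curves over a parameter grid
#'
#' @param object a `power_grid` from [power_table()]
#' @param ... unused
#' @return a ggplot of power against replicates, coloured by cv, faceted by
#'   depth and effect
#' @method autoplot power_grid
#' @export
autoplot.power_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$power,
                                   colour = factor(.data$cv))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$depth),
                        cols = ggplot2::vars(.data$effect),
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "replicates per group", y = "power", colour = "BCV") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
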