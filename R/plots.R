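#' Quadrant plot of solubility against AEx
#'
#' Scatter of QPlogS versus AEx with the class-defining axes drawn at
#' zero. Class D (lower-left quadrant, low solubility and low AEx) is the
#' aggregation-prone region of the plane.
#'
#' @param data A tibble with `qplogs`, an AEx column and optionally
#'   `group`; e.g. [apr_reference()] or `tidy(classify_dataset(...))`.
#' @param aex_col Name of the AEx column (default `"aex_printed"`, the
#'   published scores; use `"aex"` for recomputed ones).
#' @return A ggplot object.
#' @examples
#' plot_quadrants(apr_reference())
#' @export
plot_quadrants <- function(data, aex_col = "aex_printed") {
  stopifnot(aex_col %in% names(data), "qplogs" %in% names(data))
  p <- ggplot2::ggplot(
    data,
    ggplot2::aes(x = .data$qplogs, y = .data[[aex_col]])
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "QPlogS (aqueous solubility)", y = "AEx") +
    ggplot2::theme_minimal()
  if ("group" %in% names(data)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.8)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.8)
  }
  p
}

#' Plot an APR window scan
#'
#' AEx along the sequence with APR-candidate (class D) windows
#' highlighted.
#'
#' @param object An `apr_scan` tibble from [scan_protein()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.apr_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$start, y = .data$aex)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(colour = "grey60", na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$apr_flag), na.rm = TRUE) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "steelblue", `TRUE` = "firebrick"),
      name = "APR candidate"
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$seq_id), scales = "free_x") +
    ggplot2::labs(x = "window start (residue)", y = "AEx") +
    ggplot2::theme_minimal()
}
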