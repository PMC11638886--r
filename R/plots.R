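#' Volcano plot of a SOC screen
#'
#' Plots `log2(ROR)` against the negative base-10 log of the FDR-adjusted
#' p-value for every preferred term of the screened system organ class;
#' point color encodes the report count.
#'
#' @param x A `soc_screen` from [screen_soc()], or its `volcano` tibble.
#' @param fdr_line Draw a horizontal reference at this FDR level
#'   (default 0.05; `NULL` suppresses it).
#' @return A ggplot object.
#' @export
plot_volcano <- function(x, fdr_line = 0.05) {
  volcano <- if (inherits(x, "soc_screen")) x$volcano else as_tibble(x)
  dat <- filter(volcano, is.finite(log2_ror), is.finite(p_fdr))
  p <- ggplot2::ggplot(
    dat,
    ggplot2::aes(x = log2_ror, y = -log10(p_fdr), color = n)
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_color_gradient(
      low = "grey70", high = "purple4", trans = "log10"
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(
      x = expression(log[2] ~ ROR),
      y = expression(-log[10] ~ "FDR-adjusted p"),
      color = "reports"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(fdr_line)) {
    p <- p + ggplot2::geom_hline(
      yintercept = -log10(fdr_line), linetype = "dashed"
    )
  }
  p
}

#' @export
autoplot.soc_screen <- function(object, ...) plot_volcano(object, ...)

#' Kaplan--Meier cumulative-incidence plot
#'
#' Step plot of cumulative adverse-event incidence for one or more curves.
#'
#' @param curves A `km_curve`, or a named list of them (names become the
#'   group legend).
#' @return A ggplot object.
#' @export
plot_km <- function(curves) {
  if (inherits(curves, "km_curve")) curves <- list(sample = curves)
  dat <- purrr::imap(curves, function(cv, nm) {
    dplyr::bind_cols(tibble(group = nm), as_tibble(cv))
  }) %>% bind_rows()
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = day, y = cum_incidence, color = .data$group)
  ) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "days since therapy start",
      y = "cumulative incidence", color = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.km_curve <- function(object, ...) plot_km(object)

#' Annual report-count bar chart
#'
#' @param annual Tibble from [annual_counts()].
#' @return A ggplot object faceted by drug.
#' @export
plot_annual <- function(annual) {
  ggplot2::ggplot(annual, ggplot2::aes(x = year, y = n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~drug, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "reports") +
    ggplot2::theme_minimal()
}
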