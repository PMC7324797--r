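# ggplot2 summaries of the main result types.

#' Bar chart of an observed/expected profile
#'
#' One panel per context, one bar per region class, with the neutral O/E
#' of 1 marked; bars below the line indicate depletion.
#'
#' @param oe Tibble from [oe_profile()].
#' @return A ggplot object.
#' @export
plot_oe_profile <- function(oe) {
  long <- tidyr::pivot_longer(oe, dplyr::all_of(c("cpg_oe", "chg_oe", "chh_oe")),
                              names_to = "context", values_to = "oe") |>
    mutate(context = factor(.data$context, c("cpg_oe", "chg_oe", "chh_oe"),
                            c("CpG", "CHG", "CHH")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$region_class, y = .data$oe)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~context) +
    ggplot2::labs(x = NULL, y = "observed / expected") +
    ggplot2::theme_minimal()
}

#' Bar chart of stratified methylation levels
#'
#' @param summary Tibble with a `percent` column and one or two key columns
#'   (e.g. from [methylation_by_context()] or [methylation_by_feature()]).
#' @param x Name of the column mapped to the x axis.
#' @param fill Optional name of a column mapped to fill (dodged).
#' @return A ggplot object.
#' @export
plot_methylation_levels <- function(summary, x = "context", fill = NULL) {
  aes <- if (is.null(fill)) {
    ggplot2::aes(x = .data[[x]], y = .data$percent)
  } else {
    ggplot2::aes(x = .data[[x]], y = .data$percent, fill = .data[[fill]])
  }
  p <- ggplot2::ggplot(summary, aes) +
    ggplot2::labs(y = "methylation (%)", x = NULL) +
    ggplot2::theme_minimal()
  if (is.null(fill)) p + ggplot2::geom_col(fill = "grey35")
  else p + ggplot2::geom_col(position = "dodge")
}

#' Volcano plot of a differential-methylation fit
#'
#' @param object A `dml_fit` from [dml_test()].
#' @param ... Unused.
#' @return A ggplot object: methylation difference against -log10 p, with
#'   significant loci highlighted.
#' @export
autoplot.dml_fit <- function(object, ...) {
  d <- object$results
  ggplot2::ggplot(d, ggplot2::aes(x = .data$diff, y = -log10(pmax(.data$pvalue, 1e-300)),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "methylation difference (group1 - group2)",
                  y = expression(-log[10] ~ p), colour = "significant") +
    ggplot2::theme_minimal()
}
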