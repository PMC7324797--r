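# broom-style accessors for fitted objects.

#' Tidy a differential-methylation fit
#'
#' @param x A `dml_fit` from [dml_test()].
#' @param ... Unused.
#' @return The per-locus results tibble (one row per tested locus).
#' @export
tidy.dml_fit <- function(x, ...) {
  x$results
}

#' One-row summary of a differential-methylation fit
#'
#' @param x A `dml_fit` from [dml_test()].
#' @param ... Unused.
#' @return Tibble: loci tested, per-group dispersions, significant counts
#'   at the raw and BH-adjusted thresholds, and the configured alpha.
#' @export
glance.dml_fit <- function(x, ...) {
  tibble(n_loci = x$n_loci,
         phi_group1 = x$phi[1], phi_group2 = x$phi[2],
         n_significant = sum(x$results$significant),
         n_significant_adj = sum(x$results$padj < x$config$alpha),
         alpha = x$config$alpha)
}
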