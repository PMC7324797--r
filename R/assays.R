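# Plate-reader and qPCR quantification formulas: relative 5mC/5hmC percent,
# DNMT activity, and Pfaffl efficiency-corrected relative expression.

.check_pos <- function(x, what) {
  if (any(!is.finite(x) | x <= 0)) abort(sprintf("`%s` must be positive", what))
}

#' Relative 5mC percent from a colourimetric plate assay
#'
#' `[(sample OD - negative OD) / S] / [(positive OD - negative OD) * 2 / P] * 100`,
#' where S and P are the sample and positive-control DNA amounts in ng. The
#' factor 2 reflects the kit's 50%-methylated positive control. Values can
#' be negative when the sample reads below the negative control; they are
#' reported as-is (flag downstream, do not clamp).
#'
#' @param sample_od,negative_od,positive_od Optical densities.
#' @param sample_ng Sample DNA amount S (ng).
#' @param positive_ng Positive-control amount P (ng).
#' @return Numeric vector of percentages; `NA` where the positive-control
#'   denominator is not positive.
#' @export
#' @examples
#' relative_5mc_percent(0.5, 0.1, 0.9, 150, 5) # ~0.833
relative_5mc_percent <- function(sample_od, negative_od, positive_od,
                                 sample_ng, positive_ng) {
  .check_pos(sample_ng, "sample_ng"); .check_pos(positive_ng, "positive_ng")
  den <- (positive_od - negative_od) * 2 / positive_ng
  ifelse(den > 0, ((sample_od - negative_od) / sample_ng) / den * 100, NA_real_)
}

#' Relative 5hmC percent from a colourimetric plate assay
#'
#' Identical in shape to [relative_5mc_percent()] with the kit factor 5 in
#' place of 2 (the hydroxymethylation kit's positive-control scaling).
#'
#' @inheritParams relative_5mc_percent
#' @return Numeric vector of percentages; `NA` where undefined.
#' @export
relative_5hmc_percent <- function(sample_od, negative_od, positive_od,
                                  sample_ng, positive_ng) {
  .check_pos(sample_ng, "sample_ng"); .check_pos(positive_ng, "positive_ng")
  den <- (positive_od - negative_od) * 5 / positive_ng
  ifelse(den > 0, ((sample_od - negative_od) / sample_ng) / den * 100, NA_real_)
}

#' DNA methyltransferase activity in OD/h/ug
#'
#' `(sample OD - blank OD) / (protein ug * hours) * 1000`.
#'
#' @param sample_od,blank_od Optical densities.
#' @param protein_ug Protein amount (micrograms).
#' @param hours Incubation time (hours).
#' @return Numeric vector, OD per hour per microgram.
#' @export
#' @examples
#' dnmt_activity(0.5, 0.1, 10, 1) # 40
dnmt_activity <- function(sample_od, blank_od, protein_ug, hours) {
  .check_pos(protein_ug, "protein_ug"); .check_pos(hours, "hours")
  (sample_od - blank_od) / (protein_ug * hours) * 1000
}

#' Pfaffl efficiency-corrected relative expression
#'
#' `E_target^dCq_target / E_ref^dCq_ref`, with `dCq = Cq(control) -
#' Cq(sample)` and amplification efficiencies E in `[1, 2]` (2 = perfect
#' doubling). With equal efficiencies of 2 this reduces to the classic
#' `2^(dCq_target - dCq_ref)` (delta-delta-Cq) form.
#'
#' @param e_target,e_ref Amplification efficiencies in `[1, 2]`.
#' @param dcq_target,dcq_ref Cq differences (control minus sample).
#' @return Numeric vector of expression ratios.
#' @export
#' @examples
#' pfaffl_ratio(2, 1, 2, 0) # 2
pfaffl_ratio <- function(e_target, dcq_target, e_ref, dcq_ref) {
  if (any(e_target < 1 | e_target > 2 | e_ref < 1 | e_ref > 2)) {
    abort("efficiencies must lie in [1, 2]")
  }
  if (any(!is.finite(dcq_target) | !is.finite(dcq_ref))) abort("Cq differences must be finite")
  e_target^dcq_target / e_ref^dcq_ref
}

#' Pfaffl expression ratios against one or more reference genes
#'
#' Tidy wrapper: one input row per sample x reference gene (the study
#' normalised against ribosomal L27 and L32 separately).
#'
#' @param qpcr Tibble with columns `e_target`, `dcq_target`, `e_ref`,
#'   `dcq_ref` and optionally `ref_gene` and id columns, one row per
#'   sample-reference pair.
#' @return The input with a `ratio` column appended.
#' @export
pfaffl_expression <- function(qpcr) {
  qpcr <- as_tibble(qpcr)
  stopifnot(all(c("e_target", "dcq_target", "e_ref", "dcq_ref") %in% names(qpcr)))
  mutate(qpcr, ratio = pfaffl_ratio(.data$e_target, .data$dcq_target,
                                    .data$e_ref, .data$dcq_ref))
}

#' Batch 5mC/5hmC/activity calculations over a plate table
#'
#' @param plate Tibble with one row per well/sample. Columns used per
#'   assay: 5mC/5hmC need `sample_od`, `negative_od`, `positive_od`,
#'   `sample_ng`, `positive_ng`; activity needs `sample_od`, `blank_od`,
#'   `protein_ug`, `hours`.
#' @param assay One of "5mc", "5hmc", "activity".
#' @return The input with `value` (and for the percent assays a
#'   `below_negative_control` flag) appended.
#' @export
plate_assay <- function(plate, assay = c("5mc", "5hmc", "activity")) {
  assay <- match.arg(assay)
  plate <- as_tibble(plate)
  if (assay == "activity") {
    return(mutate(plate, value = dnmt_activity(.data$sample_od, .data$blank_od,
                                               .data$protein_ug, .data$hours)))
  }
  fn <- if (assay == "5mc") relative_5mc_percent else relative_5hmc_percent
  mutate(plate,
         value = fn(.data$sample_od, .data$negative_od, .data$positive_od,
                    .data$sample_ng, .data$positive_ng),
         below_negative_control = .data$value < 0)
}

#' Read a delimited plate-reader or qPCR table
#'
#' Comma- or tab-delimited text with a header row naming the fields used by
#' [plate_assay()] / [pfaffl_expression()].
#'
#' @param path Path to the file.
#' @return A tibble.
#' @export
read_assay_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("assay table not found: %s", path))
  readr::read_delim(path, delim = NULL, show_col_types = FALSE, progress = FALSE)
}

#' Mean and sample SD of replicate assay values
#'
#' @param values Numeric vector (>= 1 value).
#' @return One-row tibble `n`, `mean`, `sd` (`sd` is `NA` for n = 1).
#' @export
#' @examples
#' replicate_assay_summary(c(0.8, 0.9, 1.0))
replicate_assay_summary <- function(values) {
  if (length(values) < 1) abort("at least one value required")
  tibble(n = length(values), mean = mean(values),
         sd = if (length(values) >= 2) stats::sd(values) else NA_real_)
}
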