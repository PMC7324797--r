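# Cytosine-level methylation calls (Bismark CX cytosine reports) and
# stratified methylation summaries.

.CX_COLS <- c("contig", "pos", "strand", "count_m", "count_u", "context", "trinucleotide")

# disk (Bismark) <-> internal context spellings
.ctx_from_disk <- function(x) ifelse(x == "CG", "CpG", x)
.ctx_to_disk <- function(x) ifelse(x == "CpG", "CG", x)

#' Construct a methylome sample tibble
#'
#' A methylome sample is a tibble of strand-specific cytosine sites with
#' methylated/unmethylated call counts, sorted by (contig, pos, strand),
#' carrying `sample_id`, `group` and `replicate` attributes.
#'
#' @param sites Tibble with columns `contig`, `pos` (1-based), `strand`,
#'   `count_m`, `count_u`, `context` (CpG/CHG/CHH), `trinucleotide`.
#' @param sample_id,group,replicate Sample metadata.
#' @return The validated, sorted tibble with class `methylome`.
#' @export
methylome_sample <- function(sites, sample_id = NA_character_,
                             group = NA_character_, replicate = NA_integer_) {
  sites <- as_tibble(sites)
  stopifnot(all(.CX_COLS %in% names(sites)))
  if (any(sites$count_m < 0 | sites$count_u < 0)) abort("negative call counts")
  if (!all(sites$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  key <- paste(sites$contig, sites$pos, sites$strand)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate site key: %s", key[duplicated(key)][1]))
  }
  out <- arrange(sites, .data$contig, .data$pos, .data$strand)
  structure(out, class = c("methylome", class(out)),
            sample_id = sample_id, group = group, replicate = replicate)
}

#' Read a Bismark CX cytosine report
#'
#' Seven tab-separated columns without header: contig, 1-based position,
#' strand, methylated calls, unmethylated calls, context (CG/CHG/CHH) and
#' trinucleotide. When a genome is supplied, contexts are re-derived from
#' the sequence and mismatches reported as a warning with their count.
#'
#' @param path Path to a CX report.
#' @param genome Optional named character vector for context validation.
#' @param sample_id,group,replicate Sample metadata stored as attributes.
#' @return A `methylome` tibble (internal context spelling CpG/CHG/CHH).
#' @export
read_cx_report <- function(path, genome = NULL, sample_id = basename(path),
                           group = NA_character_, replicate = NA_integer_) {
  dat <- tryCatch(
    readr::read_tsv(path, col_names = .CX_COLS,
                    col_types = readr::cols(
                      contig = "c", pos = "i", strand = "c",
                      count_m = "i", count_u = "i",
                      context = "c", trinucleotide = "c"),
                    progress = FALSE, lazy = FALSE),
    error = function(e) abort(sprintf("CX format error in %s: %s", path, conditionMessage(e)))
  )
  if (nrow(readr::problems(dat))) {
    p <- readr::problems(dat)
    abort(sprintf("CX format error in %s (row %d): expected %s, got %s",
                  path, p$row[1], p$expected[1], p$actual[1]))
  }
  if (ncol(dat) != 7) {
    abort(sprintf("CX format error in %s: expected 7 columns, found %d", path, ncol(dat)))
  }
  if (nrow(dat) && !all(dat$context %in% c("CG", "CHG", "CHH"))) {
    abort(sprintf("CX format error in %s: context column outside {CG,CHG,CHH}", path))
  }
  dat$context <- .ctx_from_disk(dat$context)
  sample <- methylome_sample(dat, sample_id = sample_id, group = group, replicate = replicate)
  if (!is.null(genome)) {
    derived <- classify_context(genome, sample$contig, sample$pos, sample$strand)
    n_bad <- sum(derived != sample$context)
    if (n_bad > 0) {
      warn(sprintf("%d site(s) in %s have a context differing from the genome-derived context",
                   n_bad, path))
    }
  }
  sample
}

#' Write a methylome sample as a Bismark CX report
#'
#' Bit-exact inverse of [read_cx_report()]: 7-column TSV, no header, sorted,
#' Bismark context spellings, zero-coverage sites retained.
#'
#' @param sample A `methylome` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cx_report <- function(sample, path) {
  out <- sample |>
    arrange(.data$contig, .data$pos, .data$strand) |>
    mutate(context = .ctx_to_disk(.data$context)) |>
    select(dplyr::all_of(.CX_COLS))
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# pooled call-weighted percent over a site tibble
.pooled_percent <- function(sites) {
  m <- sum(as.numeric(sites$count_m)); u <- sum(as.numeric(sites$count_u))
  tibble(calls_m = m, calls_total = m + u, percent = percent_of(m, m + u))
}

#' Global (call-weighted) methylation percent
#'
#' `100 * sum(methylated calls) / sum(all calls)` over sites passing the
#' optional context filter. Zero-coverage sites contribute nothing.
#'
#' @param sample A `methylome` tibble.
#' @param context Optional context filter ("CpG", "CHG" or "CHH").
#' @return One-row tibble: `context`, `calls_m`, `calls_total`, `percent`
#'   (`NA` when no calls survive the filter).
#' @export
global_methylation_percent <- function(sample, context = NULL) {
  ctx_label <- context %||% "all"
  sub <- if (is.null(context)) sample else filter(sample, .data$context %in% !!context)
  mutate(.pooled_percent(sub), context = ctx_label, .before = 1)
}

#' Methylation percent per context
#'
#' @param sample A `methylome` tibble.
#' @return Tibble with one row per context present plus a pooled "all" row.
#' @export
methylation_by_context <- function(sample) {
  per <- sample |>
    group_by(context = .data$context) |>
    summarise(calls_m = sum(as.numeric(.data$count_m)),
              calls_total = sum(as.numeric(.data$count_m + .data$count_u)),
              .groups = "drop") |>
    mutate(percent = percent_of(.data$calls_m, .data$calls_total))
  bind_rows(per, global_methylation_percent(sample))
}

#' Methylation percent stratified by gene feature class
#'
#' Assigns every site to exactly one stratum via [classify_position()]
#' (precedence exon > intron > intergenic) and reports call-weighted
#' percents per stratum, per context and pooled across contexts.
#'
#' @param sample A `methylome` tibble.
#' @param annotation A [feature_annotation] covering the sample's contigs.
#' @param partition `"genic_intergenic"` (strata genic/intergenic) or
#'   `"exon_intron"` (strata exon/intron/intergenic).
#' @return Tibble with columns `stratum`, `context` (incl. "all"),
#'   `calls_m`, `calls_total`, `percent`.
#' @export
methylation_by_feature <- function(sample, annotation,
                                   partition = c("genic_intergenic", "exon_intron")) {
  partition <- match.arg(partition)
  missing_ct <- setdiff(unique(sample$contig), names(annotation$contig_lengths))
  if (length(missing_ct)) {
    abort(sprintf("sample contig(s) missing from annotation: %s",
                  paste(missing_ct, collapse = ", ")))
  }
  cls <- classify_position(annotation, sample$contig, sample$pos)
  stratum <- if (partition == "genic_intergenic") {
    ifelse(cls == "intergenic", "intergenic", "genic")
  } else cls
  dat <- mutate(as_tibble(sample), stratum = stratum)
  per_ctx <- dat |>
    group_by(.data$stratum, .data$context) |>
    summarise(calls_m = sum(as.numeric(.data$count_m)),
              calls_total = sum(as.numeric(.data$count_m + .data$count_u)),
              .groups = "drop")
  pooled <- dat |>
    group_by(.data$stratum) |>
    summarise(context = "all",
              calls_m = sum(as.numeric(.data$count_m)),
              calls_total = sum(as.numeric(.data$count_m + .data$count_u)),
              .groups = "drop")
  bind_rows(per_ctx, pooled) |>
    mutate(percent = percent_of(.data$calls_m, .data$calls_total)) |>
    arrange(.data$stratum, .data$context)
}

#' Strand balance report
#'
#' The field reports strand balance in two non-equivalent ways: the
#' difference in methylation level between strands (percentage points) and
#' the difference in each strand's share of all methylated calls. Both are
#' returned.
#'
#' @param sample A `methylome` tibble.
#' @return One-row tibble: per-strand percents (`percent_top` = plus
#'   strand, `percent_bottom`), their difference `level_diff_pp`, per-strand
#'   shares of methylated calls (`share_top`, `share_bottom`, in %) and
#'   `share_diff_pp`. Strata with no calls are `NA`.
#' @export
strand_report <- function(sample) {
  per <- sample |>
    group_by(.data$strand) |>
    summarise(m = sum(as.numeric(.data$count_m)),
              tot = sum(as.numeric(.data$count_m + .data$count_u)), .groups = "drop")
  g <- function(sd, col) {
    v <- per[[col]][per$strand == sd]
    if (length(v)) v else NA_real_
  }
  m_top <- g("+", "m"); m_bot <- g("-", "m")
  pct_top <- percent_of(m_top, g("+", "tot")); pct_bot <- percent_of(m_bot, g("-", "tot"))
  share_top <- percent_of(m_top, m_top + m_bot)
  share_bot <- percent_of(m_bot, m_top + m_bot)
  tibble(percent_top = pct_top, percent_bottom = pct_bot,
         level_diff_pp = pct_top - pct_bot,
         share_top = share_top, share_bottom = share_bot,
         share_diff_pp = share_top - share_bot)
}

#' Replicate mean and standard deviation of a summary statistic
#'
#' Applies a summary function (any of the summaries in this package that
#' return a tibble with a `percent` column) to each replicate and reports
#' the unweighted mean and the sample (n-1) standard deviation per stratum.
#'
#' @param samples List of `methylome` tibbles from one group.
#' @param stat Function mapping a sample to a summary tibble with a
#'   `percent` column; remaining columns other than call counts are treated
#'   as stratum keys.
#' @param ... Passed on to `stat`.
#' @return Tibble of stratum keys plus `n`, `mean`, `sd` (`sd` is `NA` for
#'   a single replicate).
#' @export
#' @examples
#' # replicate_summary(list(r1, r2, r3), global_methylation_percent)
replicate_summary <- function(samples, stat = global_methylation_percent, ...) {
  stopifnot(length(samples) >= 1)
  groups <- purrr::map_chr(samples, ~ attr(.x, "group") %||% NA_character_)
  if (length(unique(groups[!is.na(groups)])) > 1) {
    abort(sprintf("samples from mixed groups: %s",
                  paste(unique(groups[!is.na(groups)]), collapse = ", ")))
  }
  per <- purrr::imap_dfr(samples, function(s, i) mutate(stat(s, ...), .replicate = i))
  keys <- setdiff(names(per), c(".replicate", "percent", "calls_m", "calls_total"))
  per |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(n = dplyr::n(), mean = mean(.data$percent),
              sd = if (dplyr::n() >= 2) stats::sd(.data$percent) else NA_real_,
              .groups = "drop")
}
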