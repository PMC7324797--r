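# Replicate-aware differential methylation: coverage filtering, pooled
# beta-binomial dispersion, per-locus Wald test and area-statistic DMR
# calling.

#' Differential-methylation configuration
#'
#' Defaults follow the study design this package reproduces: genic CpG loci
#' with at least 10x coverage in every replicate of both groups, raw
#' p < 0.05 significance, and region-calling parameters mirroring the
#' defaults of the standard DMR tools (merge distance 100 bp, >= 3 CpG
#' sites, >= 50 bp span, >= 50% of sites significant).
#'
#' @param min_coverage Minimum per-replicate coverage (default 10).
#' @param genic_only Restrict to genic loci (default `TRUE`).
#' @param context Context tested (default "CpG").
#' @param alpha Per-locus significance threshold on the raw p (default 0.05).
#' @param merge_dist Maximum gap (bp) between significant loci merged into
#'   one region.
#' @param min_sites Minimum tested loci in a region.
#' @param min_length Minimum region span (bp).
#' @param pct_sig Minimum fraction of tested loci in the span that are
#'   significant.
#' @return A list of class `dm_config`.
#' @export
dm_config <- function(min_coverage = 10, genic_only = TRUE, context = "CpG",
                      alpha = 0.05, merge_dist = 100, min_sites = 3,
                      min_length = 50, pct_sig = 0.5) {
  stopifnot(min_coverage > 0, alpha > 0, alpha < 1, merge_dist > 0,
            min_sites > 0, min_length > 0, pct_sig > 0)
  structure(list(min_coverage = min_coverage, genic_only = genic_only,
                 context = context, alpha = alpha, merge_dist = merge_dist,
                 min_sites = min_sites, min_length = min_length,
                 pct_sig = pct_sig),
            class = "dm_config")
}

# long per-replicate count table for one group, keyed by site
.group_counts <- function(samples, context = NULL) {
  purrr::imap_dfr(samples, function(s, i) {
    d <- as_tibble(s)
    if (!is.null(context)) d <- filter(d, .data$context == !!context)
    mutate(select(d, "contig", "pos", "strand", "count_m", "count_u"),
           replicate = i, cov = .data$count_m + .data$count_u)
  })
}

#' Filter loci by context, genic location and per-replicate coverage
#'
#' Retains sites of the configured context that are covered at least
#' `min_coverage` times in every replicate of both groups, and genic when
#' `genic_only` is set.
#'
#' @param group_a,group_b Lists of `methylome` tibbles (the two groups).
#' @param annotation A [feature_annotation] (needed when `genic_only`).
#' @param config A [dm_config()].
#' @return Tibble of surviving site keys (`contig`, `pos`, `strand`),
#'   sorted; zero rows (with a warning) when nothing survives.
#' @export
filter_covered_loci <- function(group_a, group_b, annotation = NULL,
                                config = dm_config()) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  keep_of <- function(samples) {
    .group_counts(samples, config$context) |>
      group_by(.data$contig, .data$pos, .data$strand) |>
      summarise(n_rep = dplyr::n(), min_cov = min(.data$cov), .groups = "drop") |>
      filter(.data$n_rep == length(samples), .data$min_cov >= config$min_coverage) |>
      select("contig", "pos", "strand")
  }
  keys <- inner_join(keep_of(group_a), keep_of(group_b),
                     by = c("contig", "pos", "strand"))
  if (isTRUE(config$genic_only)) {
    if (is.null(annotation)) abort("`annotation` is required when `genic_only = TRUE`")
    cls <- classify_position(annotation, keys$contig, keys$pos)
    keys <- keys[cls != "intergenic", ]
  }
  keys <- arrange(keys, .data$contig, .data$pos, .data$strand)
  if (nrow(keys) == 0) warn("no locus survives the coverage/context/feature filter")
  keys
}

#' Pooled method-of-moments beta-binomial dispersion
#'
#' Estimates a single dispersion phi per group from the between-replicate
#' variability of methylation proportions, pooled across loci. Under the
#' beta-binomial model the expected between-replicate variance of the
#' proportion at a locus with coverages n_r is
#' `p(1-p) * mean_r[(1 + (n_r - 1) phi) / n_r]`; phi solves the pooled
#' moment equation (with `p(1-p)` estimated from the pooled proportion,
#' bias-corrected). Estimates below 0 are truncated to 0 (binomial).
#'
#' @param counts Long tibble from one group with columns `contig`, `pos`,
#'   `strand`, `replicate`, `count_m`, `cov` (one row per locus x
#'   replicate), e.g. built internally by [dml_test()].
#' @return A single phi >= 0. With fewer than 2 replicates, 0 with a
#'   warning.
#' @export
estimate_dispersion <- function(counts) {
  n_rep <- length(unique(counts$replicate))
  if (n_rep < 2) {
    warn("fewer than 2 replicates: dispersion fixed at 0 (binomial)")
    return(0)
  }
  wide <- counts |>
    group_by(.data$contig, .data$pos, .data$strand) |>
    filter(dplyr::n() == n_rep, all(.data$cov > 0)) |>
    summarise(p_hat = sum(.data$count_m) / sum(.data$cov),
              s2 = var(.data$count_m / .data$cov),
              mean_inv = mean(1 / .data$cov),
              mean_w = mean((.data$cov - 1) / .data$cov),
              c_num = sum(.data$cov), c_n2 = sum(.data$cov)^2,
              c_sum_n = sum(.data$cov), c_sum_nn1 = sum(.data$cov * (.data$cov - 1)),
              .groups = "drop") |>
    filter(.data$p_hat > 0, .data$p_hat < 1)
  if (nrow(wide) == 0) return(0)
  moment_gap <- function(phi) {
    # bias correction: E[p_hat(1-p_hat)] = p(1-p) (1 - c(phi)) with
    # c(phi) = sum n_r (1 + (n_r - 1) phi) / (sum n_r)^2
    cc <- (wide$c_sum_n + phi * wide$c_sum_nn1) / wide$c_n2
    pq <- wide$p_hat * (1 - wide$p_hat) / pmax(1 - cc, 1e-8)
    sum(wide$s2 - pq * (wide$mean_inv + phi * wide$mean_w))
  }
  if (moment_gap(0) <= 0) return(0)
  if (moment_gap(0.999) > 0) return(0.999)
  uniroot(moment_gap, c(0, 0.999), tol = 1e-8)$root
}

#' Per-locus Wald test for differential methylation
#'
#' For each filtered locus, group methylation means are pooled across
#' replicates (`p_g = sum(meth) / sum(cov)`), with beta-binomial variance
#' `p_g (1 - p_g) * sum_r[n_r (1 + (n_r - 1) phi_g)] / (sum_r n_r)^2`. The
#' Wald statistic is `(p_1 - p_2) / sqrt(var_1 + var_2)`, with a two-sided
#' p-value from the standard normal; a locus where both groups are jointly
#' fixed at 0 or 1 has statistic 0. Benjamini-Hochberg adjusted p-values
#' are reported alongside, but the `significant` flag (used for region
#' seeding) follows the raw p, matching the reproduced study.
#'
#' @param group_a,group_b Lists of `methylome` tibbles.
#' @param annotation Optional [feature_annotation] (required when the
#'   config restricts to genic loci).
#' @param config A [dm_config()].
#' @param dispersion Optional numeric length 2 (phi for group A and B);
#'   estimated from the data when `NULL`.
#' @return An object of class `dml_fit`: list with `results` (tibble of
#'   per-locus statistics, sorted by contig/pos/strand), `phi`, `config`,
#'   `n_loci` and `skipped` (loci dropped for zero group coverage).
#' @export
dml_test <- function(group_a, group_b, annotation = NULL, config = dm_config(),
                     dispersion = NULL) {
  keys <- filter_covered_loci(group_a, group_b, annotation, config)
  ca <- inner_join(.group_counts(group_a, config$context), keys,
                   by = c("contig", "pos", "strand"))
  cb <- inner_join(.group_counts(group_b, config$context), keys,
                   by = c("contig", "pos", "strand"))
  if (is.null(dispersion)) {
    dispersion <- c(estimate_dispersion(ca), estimate_dispersion(cb))
  } else {
    stopifnot(is.numeric(dispersion), length(dispersion) == 2, all(dispersion >= 0))
  }
  summ <- function(counts, phi) {
    counts |>
      group_by(.data$contig, .data$pos, .data$strand) |>
      summarise(m = sum(.data$count_m), n = sum(.data$cov),
                vnum = sum(.data$cov * (1 + (.data$cov - 1) * phi)),
                .groups = "drop") |>
      mutate(mu = ifelse(.data$n > 0, .data$m / .data$n, NA_real_),
             v = .data$mu * (1 - .data$mu) * .data$vnum / .data$n^2)
  }
  a <- summ(ca, dispersion[1]); b <- summ(cb, dispersion[2])
  res <- inner_join(a, b, by = c("contig", "pos", "strand"), suffix = c("1", "2"))
  skipped <- filter(res, .data$n1 == 0 | .data$n2 == 0) |>
    mutate(reason = "zero coverage in one group") |>
    select("contig", "pos", "strand", "reason")
  res <- res |>
    filter(.data$n1 > 0, .data$n2 > 0) |>
    mutate(diff = .data$mu1 - .data$mu2,
           se = sqrt(.data$v1 + .data$v2),
           stat = dplyr::case_when(
             .data$mu1 == .data$mu2 & .data$mu1 %in% c(0, 1) ~ 0,
             .data$se > 0 ~ .data$diff / .data$se,
             TRUE ~ 0),
           pvalue = 2 * pnorm(-abs(.data$stat)),
           padj = p.adjust(.data$pvalue, method = "BH"),
           significant = .data$pvalue < config$alpha) |>
    select("contig", "pos", "strand", "mu1", "mu2", "diff", "se",
           "stat", "pvalue", "padj", "significant") |>
    arrange(.data$contig, .data$pos, .data$strand)
  structure(list(results = res, phi = dispersion, config = config,
                 n_loci = nrow(res), skipped = skipped),
            class = "dml_fit")
}

#' @export
print.dml_fit <- function(x, ...) {
  cat(sprintf("<dml_fit> %d loci tested; phi = (%.4f, %.4f); %d significant at p < %g\n",
              x$n_loci, x$phi[1], x$phi[2], sum(x$results$significant), x$config$alpha))
  invisible(x)
}

#' Call differentially methylated regions with an area statistic
#'
#' Significant same-sign loci are merged into candidate regions while the
#' gap between consecutive significant loci is at most `merge_dist`. A
#' region spans its first to last significant locus; `n_cg` counts all
#' tested loci inside the span and `pct_sig` the significant fraction among
#' them. Regions are kept when `n_cg >= min_sites`, span `>= min_length`
#' and `pct_sig >= pct_sig`. The area statistic is the sum of the Wald
#' statistics of all tested loci in the span; output is sorted by
#' decreasing |areaStat| (coordinate order breaking ties).
#'
#' @param dml A `dml_fit` or its per-locus results tibble (sorted).
#' @param config A [dm_config()].
#' @return Tibble: `contig`, `start`, `end` (1-based inclusive), `n_cg`,
#'   `n_sig`, `pct_sig`, `area_stat`, `mean_diff`, `direction`.
#' @export
call_dmr <- function(dml, config = NULL) {
  if (inherits(dml, "dml_fit")) {
    config <- config %||% dml$config
    dml <- dml$results
  }
  config <- config %||% dm_config()
  out <- tibble(contig = character(), start = integer(), end = integer(),
                n_cg = integer(), n_sig = integer(), pct_sig = double(),
                area_stat = double(), mean_diff = double(), direction = character())
  if (nrow(dml) == 0) return(out)
  dml <- arrange(dml, .data$contig, .data$pos)
  for (ct in unique(dml$contig)) {
    d <- filter(dml, .data$contig == ct)
    sig <- filter(d, .data$significant)
    if (nrow(sig) == 0) next
    # new cluster when gap > merge_dist or the difference changes sign
    sgn <- sign(sig$diff)
    new_cluster <- c(TRUE, diff(sig$pos) > config$merge_dist | sgn[-1] != head(sgn, -1))
    cl <- cumsum(new_cluster)
    for (k in unique(cl)) {
      s <- sig[cl == k, ]
      span <- filter(d, .data$pos >= min(s$pos), .data$pos <= max(s$pos))
      n_cg <- nrow(span); n_sig <- nrow(s)
      frac <- n_sig / n_cg
      len <- max(s$pos) - min(s$pos) + 1L
      if (n_cg < config$min_sites || len < config$min_length || frac < config$pct_sig) next
      out <- bind_rows(out, tibble(
        contig = ct, start = as.integer(min(s$pos)), end = as.integer(max(s$pos)),
        n_cg = n_cg, n_sig = n_sig, pct_sig = frac,
        area_stat = sum(span$stat), mean_diff = mean(span$diff),
        direction = if (sgn[cl == k][1] > 0) "hyper" else "hypo"))
    }
  }
  arrange(out, dplyr::desc(abs(.data$area_stat)), .data$contig, .data$start)
}

#' Map differentially methylated regions to genes
#'
#' A gene is differentially methylated (a DME) when at least one region
#' overlaps its span by >= 1 bp.
#'
#' @param regions Tibble from [call_dmr()].
#' @param annotation A [feature_annotation].
#' @return Tibble: `gene_id`, `n_regions`, `area_stat_sum`, sorted by
#'   decreasing |area_stat_sum|.
#' @export
map_regions_to_genes <- function(regions, annotation) {
  stopifnot(inherits(annotation, "feature_annotation"))
  genes <- annotation$genes
  if (nrow(regions) == 0 || nrow(genes) == 0) {
    return(tibble(gene_id = character(), n_regions = integer(),
                  area_stat_sum = double()))
  }
  rgr <- GenomicRanges::GRanges(regions$contig, IRanges::IRanges(regions$start, regions$end))
  ggr <- GenomicRanges::GRanges(genes$contig, IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(rgr, ggr)
  if (length(hits) == 0) {
    return(tibble(gene_id = character(), n_regions = integer(),
                  area_stat_sum = double()))
  }
  tibble(gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
         area_stat = regions$area_stat[S4Vectors::queryHits(hits)]) |>
    group_by(.data$gene_id) |>
    summarise(n_regions = dplyr::n(), area_stat_sum = sum(.data$area_stat),
              .groups = "drop") |>
    arrange(dplyr::desc(abs(.data$area_stat_sum)), .data$gene_id)
}

#' Write DMRs as BED6+ (0-based half-open starts)
#'
#' @param regions Tibble from [call_dmr()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(regions, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%.4f\t.\t%d\t%.3f\t%.4f",
                   regions$contig, regions$start - 1L, regions$end,
                   paste0("dmr_", seq_len(nrow(regions))),
                   regions$area_stat, regions$n_cg, regions$pct_sig,
                   regions$mean_diff)
  writeLines(lines, path)
  invisible(path)
}
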