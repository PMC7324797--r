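# File-level orchestration behind the command-line interface: each run_*
# function reads standard formats, calls the analysis functions and writes
# TSV/JSON/BED outputs with a provenance header.

.pkg_version <- function() as.character(utils::packageVersion("bsmethyl"))

.provenance <- function(seed = NA) {
  sprintf("# bsmethyl %s | seed=%s | %s", .pkg_version(),
          ifelse(is.na(seed), "NA", seed), format(Sys.time(), "%Y-%m-%d"))
}

.write_result_tsv <- function(x, path, seed = NA) {
  con <- file(path, "w")
  writeLines(.provenance(seed), con)
  close(con)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Run the simulator and write an experiment directory
#'
#' @param preset Preset name (see [sim_preset()]), or `NULL` to use `config`.
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param config Optional [sim_config()] overriding the preset.
#' @return The experiment, invisibly.
#' @export
run_simulate <- function(preset = "context", out_dir, seed = 42L, config = NULL) {
  cfg <- config %||% sim_preset(preset, seed = seed)
  ex <- simulate_experiment(cfg)
  write_experiment(ex, out_dir)
  invisible(ex)
}

#' Profile methylomes: global, per-context, per-strand, per-feature
#'
#' Reads one or more CX reports (one per replicate of one group), computes
#' the stratified summaries and the replicate mean +/- SD, and writes them
#' as TSVs to `out_dir`. Without an annotation the feature strata are
#' skipped with a warning and the remaining summaries still produced.
#'
#' @param cx_paths Character vector of CX report paths.
#' @param genome_path Optional FASTA (context validation on load).
#' @param gff_path Optional GFF3 (feature strata).
#' @param out_dir Output directory.
#' @param seed Seed recorded in output headers (provenance only).
#' @return Named list of the summary tibbles, invisibly.
#' @export
run_profile <- function(cx_paths, genome_path = NULL, gff_path = NULL,
                        out_dir, seed = NA) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- if (!is.null(genome_path)) read_fasta(genome_path)
  samples <- purrr::imap(cx_paths, function(p, i) {
    read_cx_report(p, genome = genome, replicate = i)
  })
  pooled <- methylome_sample(
    purrr::map_dfr(samples, as_tibble) |>
      group_by(.data$contig, .data$pos, .data$strand, .data$context, .data$trinucleotide) |>
      summarise(count_m = sum(.data$count_m), count_u = sum(.data$count_u),
                .groups = "drop"),
    sample_id = "pooled")
  out <- list(
    global = global_methylation_percent(pooled),
    by_context = methylation_by_context(pooled),
    by_strand = strand_report(pooled),
    replicate_global = replicate_summary(samples, global_methylation_percent),
    replicate_by_context = replicate_summary(samples, methylation_by_context)
  )
  if (!is.null(gff_path)) {
    if (is.null(genome)) abort("`genome_path` is required to use `gff_path`")
    ann <- read_gff3(gff_path, genome)
    out$by_feature_genic <- methylation_by_feature(pooled, ann, "genic_intergenic")
    out$by_feature_exon <- methylation_by_feature(pooled, ann, "exon_intron")
  } else {
    warn("no GFF3 supplied: feature strata omitted")
  }
  purrr::iwalk(out, function(x, nm) {
    .write_result_tsv(x, file.path(out_dir, paste0(nm, ".tsv")), seed)
  })
  jsonlite::write_json(out, file.path(out_dir, "profile.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out)
}

#' Observed/expected profile of a genome against its annotation
#'
#' @param genome_path FASTA path.
#' @param gff_path GFF3 path.
#' @param out_dir Output directory.
#' @param classes Region classes to profile.
#' @param seed Seed recorded in the output header (provenance only).
#' @return The O/E tibble, invisibly.
#' @export
run_oe <- function(genome_path, gff_path, out_dir,
                   classes = c("genome", "genic", "intergenic", "exon", "intron"),
                   seed = NA) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- read_fasta(genome_path)
  ann <- read_gff3(gff_path, genome)
  oe <- oe_profile(genome, ann, classes = classes)
  .write_result_tsv(oe, file.path(out_dir, "oe_profile.tsv"), seed)
  invisible(oe)
}

#' Differential methylation between two groups of CX reports
#'
#' Wraps [dml_test()], [call_dmr()] and [map_regions_to_genes()] with the
#' study defaults (genic CpG loci, >= 10x in every replicate, alpha 0.05)
#' and writes the DML table (TSV), DMR regions (BED6+) and DME gene list.
#'
#' @param group_a_paths,group_b_paths CX report paths for the two groups.
#' @param genome_path FASTA path.
#' @param gff_path GFF3 path.
#' @param out_dir Output directory.
#' @param config A [dm_config()].
#' @param seed Seed recorded in output headers (provenance only).
#' @return List with `fit`, `regions`, `genes`, invisibly.
#' @export
run_diff <- function(group_a_paths, group_b_paths, genome_path, gff_path,
                     out_dir, config = dm_config(), seed = NA) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- read_fasta(genome_path)
  ann <- read_gff3(gff_path, genome)
  ga <- purrr::imap(group_a_paths, ~ read_cx_report(.x, group = "A", replicate = .y))
  gb <- purrr::imap(group_b_paths, ~ read_cx_report(.x, group = "B", replicate = .y))
  fit <- dml_test(ga, gb, annotation = ann, config = config)
  regions <- call_dmr(fit)
  genes <- map_regions_to_genes(regions, ann)
  .write_result_tsv(tidy(fit), file.path(out_dir, "dml.tsv"), seed)
  write_dmr_bed(regions, file.path(out_dir, "dmr.bed"))
  .write_result_tsv(genes, file.path(out_dir, "dme_genes.tsv"), seed)
  invisible(list(fit = fit, regions = regions, genes = genes))
}

#' Batch assay calculations over a delimited table
#'
#' @param path Delimited input (see [read_assay_table()]).
#' @param assay One of "5mc", "5hmc", "activity", "pfaffl".
#' @param out_dir Output directory.
#' @param group_col Optional column to summarise replicates by.
#' @param seed Seed recorded in the output header (provenance only).
#' @return List with `results` and `summary`, invisibly.
#' @export
run_assay <- function(path, assay = c("5mc", "5hmc", "activity", "pfaffl"),
                      out_dir, group_col = NULL, seed = NA) {
  assay <- match.arg(assay)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- read_assay_table(path)
  res <- if (assay == "pfaffl") {
    rename(pfaffl_expression(tab), value = "ratio")
  } else {
    plate_assay(tab, assay)
  }
  summary <- if (!is.null(group_col)) {
    res |>
      group_by(across(dplyr::all_of(group_col))) |>
      summarise(replicate_assay_summary(.data$value), .groups = "drop")
  } else {
    replicate_assay_summary(res$value)
  }
  .write_result_tsv(res, file.path(out_dir, paste0("assay_", assay, ".tsv")), seed)
  .write_result_tsv(summary, file.path(out_dir, paste0("assay_", assay, "_summary.tsv")), seed)
  invisible(list(results = res, summary = summary))
}
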