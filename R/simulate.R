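# Seeded bisulfite-methylome simulator with planted, recoverable
# parameters: genome, gene annotation, and per-replicate cytosine-level
# call counts under a beta-binomial replicate model.

#' Simulation configuration
#'
#' Defines a synthetic WGBS experiment: an i.i.d. genome at a given GC
#' fraction, a deterministic gene geometry, a methylation model of
#' per-stratum success probabilities, replicate-level beta-binomial
#' dispersion, a negative-binomial coverage model, bisulfite conversion
#' errors, and optional planted differentially methylated regions.
#'
#' The methylation model `meth_rules` is a tibble with columns `context`
#' ("CpG"/"CHG"/"CHH" or "*"), `feature` ("exon"/"intron"/"intergenic"/
#' "genic" or "*"), `strand` ("+"/"-" or "*") and `prob`; the first
#' matching rule (top to bottom) sets a site's planted probability.
#' Planted DMRs (`dmrs`: tibble `contig`, `start`, `end`, `group`, `prob`)
#' override the CpG probability inside the region for the named group.
#'
#' @param seed Integer seed; all outputs are deterministic given it.
#' @param contig_lengths Named integer vector.
#' @param gc GC fraction of the i.i.d. genome.
#' @param n_genes,exons_per_gene,exon_length,intron_length Gene geometry;
#'   genes are placed at regular intervals, strands alternating.
#' @param meth_rules Methylation model (see Details).
#' @param phi Replicate-level beta-binomial dispersion (0 = binomial).
#' @param coverage_mean,coverage_overdispersion Negative-binomial coverage
#'   (variance `mu + od * mu^2`); overdispersion 0 gives Poisson.
#' @param nonconversion Probability an unmethylated cytosine escapes
#'   conversion and is read as methylated.
#' @param conversion_error Probability a methylated cytosine is
#'   inappropriately converted (read unmethylated).
#' @param replicates Biological replicates per group.
#' @param groups Group labels.
#' @param dmrs Planted DMR table (see Details), or `NULL`.
#' @param cpg_depletion Probability that the G of an exonic CpG dinucleotide
#'   is mutated away (emulates exonic CpG depletion); 0 disables.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       contig_lengths = c(chr1 = 100000L),
                       gc = 0.4,
                       n_genes = 10L, exons_per_gene = 3L,
                       exon_length = 500L, intron_length = 750L,
                       meth_rules = tibble(context = "*", feature = "*",
                                           strand = "*", prob = 0.01),
                       phi = 0.02,
                       coverage_mean = 30, coverage_overdispersion = 0.1,
                       nonconversion = 0, conversion_error = 0,
                       replicates = 3L, groups = "A",
                       dmrs = NULL, cpg_depletion = 0) {
  meth_rules <- as_tibble(meth_rules)
  stopifnot(all(c("context", "feature", "strand", "prob") %in% names(meth_rules)),
            all(meth_rules$prob >= 0 & meth_rules$prob <= 1),
            phi >= 0, phi < 1, coverage_mean > 0, coverage_overdispersion >= 0,
            nonconversion >= 0, nonconversion <= 1,
            conversion_error >= 0, conversion_error <= 1,
            gc > 0, gc < 1, replicates >= 1)
  if (!is.null(dmrs)) {
    dmrs <- as_tibble(dmrs)
    stopifnot(all(c("contig", "start", "end", "group", "prob") %in% names(dmrs)),
              all(dmrs$prob >= 0 & dmrs$prob <= 1),
              all(dmrs$group %in% groups))
  }
  structure(list(seed = as.integer(seed), contig_lengths = contig_lengths, gc = gc,
                 n_genes = n_genes, exons_per_gene = exons_per_gene,
                 exon_length = exon_length, intron_length = intron_length,
                 meth_rules = meth_rules, phi = phi,
                 coverage_mean = coverage_mean,
                 coverage_overdispersion = coverage_overdispersion,
                 nonconversion = nonconversion, conversion_error = conversion_error,
                 replicates = as.integer(replicates), groups = groups,
                 dmrs = dmrs, cpg_depletion = cpg_depletion),
            class = "sim_config")
}

# deterministic gene geometry shared by simulate_annotation and the CpG
# depletion step
.gene_layout <- function(config) {
  gene_len <- config$exons_per_gene * config$exon_length +
    (config$exons_per_gene - 1L) * config$intron_length
  empty <- tibble(gene_id = character(), contig = character(),
                  strand = character(), start = integer(), end = integer())
  bind_rows(empty, purrr::map_dfr(names(config$contig_lengths), function(ct) {
    L <- config$contig_lengths[[ct]]
    ng <- config$n_genes
    if (ng == 0) return(empty)
    spacing <- L %/% ng
    if (gene_len >= spacing) abort("gene geometry does not fit the contig")
    offset <- (spacing - gene_len) %/% 2L
    start <- (seq_len(ng) - 1L) * spacing + offset + 1L
    tibble(gene_id = sprintf("%s_g%04d", ct, seq_len(ng)), contig = ct,
           strand = rep_len(c("+", "-"), ng),
           start = as.integer(start), end = as.integer(start + gene_len - 1L))
  }))
}

.exon_layout <- function(genes, config) {
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    s <- genes$start[i]
    e_start <- s + (seq_len(config$exons_per_gene) - 1L) *
      (config$exon_length + config$intron_length)
    tibble(gene_id = genes$gene_id[i], contig = genes$contig[i],
           start = as.integer(e_start),
           end = as.integer(e_start + config$exon_length - 1L))
  })
}

#' Simulate an i.i.d. genome
#'
#' Bases are drawn independently with P(G) = P(C) = gc/2. With
#' `cpg_depletion > 0`, the G of each CpG dinucleotide lying fully inside
#' an exon (per the config's deterministic gene geometry) is replaced by a
#' random non-G base with that probability.
#'
#' @param config A [sim_config()].
#' @return Named character vector of sequences.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  probs <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2, (1 - config$gc) / 2)
  codes <- utf8ToInt("ACGT")
  genome <- vapply(names(config$contig_lengths), function(ct) {
    idx <- sample.int(4L, config$contig_lengths[[ct]], replace = TRUE, prob = probs)
    intToUtf8(codes[idx])
  }, character(1))
  if (config$cpg_depletion > 0 && config$n_genes > 0) {
    exons <- .exon_layout(.gene_layout(config), config)
    for (ct in names(genome)) {
      b <- seq_to_raw(genome[[ct]])
      cg <- which(b[-length(b)] == .BASE_C & b[-1] == .BASE_G)
      ex <- exons[exons$contig == ct, ]
      in_exon <- rep(FALSE, length(cg))
      for (j in seq_len(nrow(ex))) {
        in_exon <- in_exon | (cg >= ex$start[j] & cg + 1L <= ex$end[j])
      }
      hit <- cg[in_exon][runif(sum(in_exon)) < config$cpg_depletion]
      if (length(hit)) {
        b[hit + 1L] <- c(.BASE_A, .BASE_C, .BASE_T)[sample.int(3L, length(hit), replace = TRUE)]
        genome[[ct]] <- raw_to_seq(b)
      }
    }
  }
  genome
}

#' Simulate a gene annotation
#'
#' Genes with alternating exon/intron structure are placed deterministically
#' at regular intervals along each contig, strands alternating.
#'
#' @param genome Named character vector (for contig lengths).
#' @param config A [sim_config()].
#' @return A [feature_annotation].
#' @export
simulate_annotation <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- .gene_layout(config)
  exons <- if (nrow(genes)) .exon_layout(genes, config) else
    tibble(gene_id = character(), contig = character(), start = integer(), end = integer())
  feature_annotation(genes, exons, contig_lengths(genome))
}

# planted probability per site for one group: first matching rule wins,
# then DMR overrides (CpG sites only)
.planted_prob <- function(sites, feature, config, group) {
  p <- rep(NA_real_, nrow(sites))
  rules <- config$meth_rules
  for (i in rev(seq_len(nrow(rules)))) {
    r <- rules[i, ]
    ok <- (r$context == "*" | sites$context == r$context) &
      (r$strand == "*" | sites$strand == r$strand) &
      (r$feature == "*" |
         (r$feature == "genic" & feature != "intergenic") |
         feature == r$feature)
    p[ok] <- r$prob
  }
  if (anyNA(p)) abort("methylation model leaves site strata without a probability")
  if (!is.null(config$dmrs)) {
    d <- config$dmrs[config$dmrs$group == group, ]
    for (i in seq_len(nrow(d))) {
      ok <- sites$contig == d$contig[i] & sites$pos >= d$start[i] &
        sites$pos <= d$end[i] & sites$context == "CpG"
      p[ok] <- d$prob[i]
    }
  }
  p
}

# cytosine site table with feature class (cached by simulate_experiment)
.site_table <- function(genome, annotation) {
  sites <- enumerate_cytosines(genome)
  sites <- sites[sites$context != "UNDEFINED", ]
  sites$feature <- classify_position(annotation, sites$contig, sites$pos)
  sites
}

#' Simulate one replicate methylome
#'
#' For every defined-context cytosine: the planted probability p comes from
#' the methylation model (with DMR overrides for the given group); the
#' replicate-level rate is drawn from a Beta with mean p and dispersion phi
#' (phi = 0 keeps p); coverage is negative-binomial; methylated calls are
#' binomial at `p_r (1 - conversion_error) + (1 - p_r) nonconversion`.
#' Fully deterministic given (config seed, group, replicate).
#'
#' @param genome Named character vector.
#' @param annotation A [feature_annotation].
#' @param config A [sim_config()].
#' @param group Group label (must be in `config$groups`).
#' @param replicate Replicate number (1-based).
#' @param sites Optional precomputed site table (internal reuse).
#' @return List with `sample` (a `methylome` tibble) and `truth` (tibble of
#'   per-site planted probabilities with feature class).
#' @export
simulate_methylome <- function(genome, annotation, config, group = "A",
                               replicate = 1L, sites = NULL) {
  stopifnot(inherits(config, "sim_config"))
  gi <- match(group, config$groups)
  if (is.na(gi)) abort(sprintf("unknown group '%s'", group))
  if (!is.null(config$dmrs)) {
    lens <- contig_lengths(genome)
    if (any(!config$dmrs$contig %in% names(lens)) ||
        any(config$dmrs$start < 1 | config$dmrs$end > lens[config$dmrs$contig])) {
      abort("planted DMR outside genome bounds")
    }
  }
  if (is.null(sites)) sites <- .site_table(genome, annotation)
  p <- .planted_prob(sites, sites$feature, config, group)
  set.seed(derive_seed(config$seed, 100L + gi, replicate))
  n_sites <- nrow(sites)
  p_r <- p
  if (config$phi > 0) {
    mid <- p > 0 & p < 1
    a <- p[mid] * (1 - config$phi) / config$phi
    b <- (1 - p[mid]) * (1 - config$phi) / config$phi
    p_r[mid] <- rbeta(sum(mid), a, b)
  }
  cov <- if (config$coverage_overdispersion > 0) {
    rnbinom(n_sites, mu = config$coverage_mean, size = 1 / config$coverage_overdispersion)
  } else {
    rpois(n_sites, config$coverage_mean)
  }
  eff <- p_r * (1 - config$conversion_error) + (1 - p_r) * config$nonconversion
  m <- rbinom(n_sites, cov, eff)
  sample <- methylome_sample(
    tibble(contig = sites$contig, pos = sites$pos, strand = sites$strand,
           count_m = m, count_u = cov - m,
           context = sites$context, trinucleotide = sites$trinucleotide),
    sample_id = sprintf("%s_rep%d", group, replicate),
    group = group, replicate = as.integer(replicate))
  truth <- tibble(contig = sites$contig, pos = sites$pos, strand = sites$strand,
                  context = sites$context, feature = sites$feature, p_planted = p)
  list(sample = sample, truth = truth)
}

#' Simulate a full multi-group, multi-replicate experiment
#'
#' @param config A [sim_config()].
#' @return List of class `sim_experiment`: `genome`, `annotation`,
#'   `samples` (nested list `samples[[group]][[replicate]]`), `truth`
#'   (per-group planted-probability tibbles), `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- simulate_genome(config)
  annotation <- simulate_annotation(genome, config)
  sites <- .site_table(genome, annotation)
  samples <- list(); truth <- list()
  for (g in config$groups) {
    reps <- purrr::map(seq_len(config$replicates), function(r) {
      simulate_methylome(genome, annotation, config, group = g, replicate = r,
                         sites = sites)
    })
    samples[[g]] <- purrr::map(reps, "sample")
    truth[[g]] <- reps[[1]]$truth
  }
  structure(list(genome = genome, annotation = annotation, samples = samples,
                 truth = truth, config = config),
            class = "sim_experiment")
}

#' Named simulation presets
#'
#' Five ready-made configurations that emulate the reported structure of an
#' aphid WGBS study:
#' \describe{
#'   \item{context}{Per-context planted levels CpG 5.19%, CHG 0.27%,
#'     CHH 0.34% on a 2 Mb genome.}
#'   \item{feature}{Per-feature levels genic 1.58%, intergenic 0.808% (all
#'     contexts) on a 2.5 Mb genome.}
#'   \item{global}{A uniform 1.126% at every cytosine on a 1.25 Mb genome.}
#'   \item{dmr-null}{Two identical groups (genic CpG level 0.30,
#'     phi = 0.02) with no planted regions, for type-I-error calibration.}
#'   \item{dmr-alt}{dmr-null plus 20 planted 2 kb genic DMRs where group B
#'     is shifted +0.30 (0.30 to 0.60).}
#' }
#' All presets use 3 replicates per group, negative-binomial coverage with
#' mean 30 and overdispersion 0.1, replicate dispersion phi = 0.02, GC 0.4
#' and zero conversion error.
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
sim_preset <- function(name = c("context", "feature", "global", "dmr-null", "dmr-alt"),
                       seed = 42L) {
  name <- match.arg(name)
  rules <- function(...) {
    m <- matrix(c(...), ncol = 4, byrow = TRUE)
    tibble(context = m[, 1], feature = m[, 2], strand = m[, 3],
           prob = as.numeric(m[, 4]))
  }
  base <- function(len, n_genes, meth_rules, groups = "A", dmrs = NULL) {
    sim_config(seed = seed, contig_lengths = c(chr1 = as.integer(len)),
               gc = 0.4, n_genes = n_genes, exons_per_gene = 3L,
               exon_length = 500L, intron_length = 750L,
               meth_rules = meth_rules, phi = 0.02,
               coverage_mean = 30, coverage_overdispersion = 0.1,
               replicates = 3L, groups = groups, dmrs = dmrs)
  }
  switch(name,
    "context" = base(2e6, 100L, rules("CpG", "*", "*", 0.0519,
                                      "CHG", "*", "*", 0.0027,
                                      "CHH", "*", "*", 0.0034)),
    "feature" = base(2.5e6, 125L, rules("*", "genic", "*", 0.0158,
                                        "*", "intergenic", "*", 0.00808)),
    "global" = base(1.25e6, 60L, rules("*", "*", "*", 0.01126)),
    "dmr-null" = base(1e6, 133L, rules("CpG", "genic", "*", 0.30,
                                       "CpG", "intergenic", "*", 0.05,
                                       "CHG", "*", "*", 0.003,
                                       "CHH", "*", "*", 0.003),
                      groups = c("A", "B")),
    "dmr-alt" = {
      cfg <- base(1e6, 133L, rules("CpG", "genic", "*", 0.30,
                                   "CpG", "intergenic", "*", 0.05,
                                   "CHG", "*", "*", 0.003,
                                   "CHH", "*", "*", 0.003),
                  groups = c("A", "B"))
      genes <- .gene_layout(cfg)[1:20, ]
      cfg$dmrs <- tibble(contig = genes$contig,
                         start = genes$start + 200L,
                         end = genes$start + 2199L,
                         group = "B", prob = 0.60)
      cfg
    })
}

#' Write a simulated experiment to disk
#'
#' Emits FASTA, GFF3, one CX report per group/replicate, per-group truth
#' tables (TSV) and the exact configuration with seed (YAML).
#'
#' @param experiment A `sim_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "sim_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(experiment$genome, file.path(dir, "genome.fa"))
  write_gff3(experiment$annotation, file.path(dir, "genes.gff3"))
  for (g in names(experiment$samples)) {
    for (r in seq_along(experiment$samples[[g]])) {
      write_cx_report(experiment$samples[[g]][[r]],
                      file.path(dir, sprintf("%s_rep%d.CX_report.txt", g, r)))
    }
    readr::write_tsv(experiment$truth[[g]], file.path(dir, sprintf("truth_%s.tsv", g)),
                     progress = FALSE)
  }
  cfg <- experiment$config
  cfg$meth_rules <- as.data.frame(cfg$meth_rules)
  if (!is.null(cfg$dmrs)) cfg$dmrs <- as.data.frame(cfg$dmrs)
  cfg$contig_lengths <- as.list(cfg$contig_lengths)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
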