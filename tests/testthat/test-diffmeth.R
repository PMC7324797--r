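# helper: one group of replicate samples from matrices of counts/coverages
group_from_matrices <- function(pos, m, cov, group = "A") {
  lapply(seq_len(ncol(m)), function(r) {
    counts_sample(pos, m[, r], cov[, r], group = group, replicate = r)
  })
}

test_that("coverage filter requires the threshold in every replicate of both groups", {
  pos <- c(100, 200)
  a <- group_from_matrices(pos, matrix(1, 2, 3), matrix(10, 2, 3))
  covb <- matrix(10, 2, 3); covb[2, 3] <- 9 # site 2 dips below 10x in one replicate
  b <- group_from_matrices(pos, matrix(1, 2, 3), covb, group = "B")
  keys <- filter_covered_loci(a, b, config = dm_config(genic_only = FALSE))
  expect_equal(keys$pos, 100)

  # intergenic CpG with ample coverage is dropped under genic_only
  ann <- toy_annotation()
  a2 <- group_from_matrices(c(50, 120), matrix(2, 2, 3), matrix(20, 2, 3))
  b2 <- group_from_matrices(c(50, 120), matrix(2, 2, 3), matrix(20, 2, 3), "B")
  keys2 <- filter_covered_loci(a2, b2, ann, dm_config(genic_only = TRUE))
  expect_equal(keys2$pos, 50)

  expect_warning(
    filter_covered_loci(a, b, config = dm_config(min_coverage = 100, genic_only = FALSE)),
    "no locus survives")
})

test_that("coverage filter matches a brute-force recount on simulated data", {
  cfg <- sim_preset("dmr-null", seed = 77)
  cfg$contig_lengths <- c(chr1 = 60000L); cfg$n_genes <- 8L
  ex <- simulate_experiment(cfg)
  config <- dm_config()
  keys <- filter_covered_loci(ex$samples$A, ex$samples$B, ex$annotation, config)

  # oracle: join all six replicates site-wise and recount with base R
  all_reps <- c(ex$samples$A, ex$samples$B)
  tabs <- lapply(all_reps, function(s) {
    s <- s[s$context == "CpG", ]
    data.frame(key = paste(s$contig, s$pos, s$strand), cov = s$count_m + s$count_u)
  })
  key_union <- unique(unlist(lapply(tabs, `[[`, "key")))
  ok <- rep(TRUE, length(key_union))
  for (t in tabs) {
    cov <- t$cov[match(key_union, t$key)]
    ok <- ok & !is.na(cov) & cov >= config$min_coverage
  }
  keep <- key_union[ok]
  parts <- do.call(rbind, strsplit(keep, " "))
  genic <- classify_position(ex$annotation, parts[, 1], as.integer(parts[, 2])) != "intergenic"
  expect_setequal(paste(keys$contig, keys$pos, keys$strand), keep[genic])
})

test_that("Wald statistic matches hand arithmetic and degenerate rules", {
  pos <- 1:2
  # identical counts in both groups -> stat 0, p 1
  a <- group_from_matrices(pos, matrix(5, 2, 3), matrix(20, 2, 3))
  b <- group_from_matrices(pos, matrix(5, 2, 3), matrix(20, 2, 3), "B")
  fit <- dml_test(a, b, config = dm_config(genic_only = FALSE), dispersion = c(0, 0))
  expect_equal(fit$results$stat, c(0, 0))
  expect_equal(fit$results$pvalue, c(1, 1))

  # (50,100) x3 vs (10,100) x3 at phi = 0
  a2 <- group_from_matrices(1, matrix(50, 1, 3), matrix(100, 1, 3))
  b2 <- group_from_matrices(1, matrix(10, 1, 3), matrix(100, 1, 3), "B")
  fit2 <- dml_test(a2, b2, config = dm_config(genic_only = FALSE), dispersion = c(0, 0))
  se_hand <- sqrt(0.5 * 0.5 / 300 + 0.1 * 0.9 / 300)
  expect_equal(fit2$results$stat, 0.4 / se_hand, tolerance = 1e-12)
  expect_equal(fit2$results$mu1, 0.5)
  expect_equal(fit2$results$mu2, 0.1)

  # jointly fixed proportions define stat = 0 rather than 0/0
  a3 <- group_from_matrices(1, matrix(0, 1, 3), matrix(30, 1, 3))
  b3 <- group_from_matrices(1, matrix(0, 1, 3), matrix(30, 1, 3), "B")
  fit3 <- dml_test(a3, b3, config = dm_config(genic_only = FALSE), dispersion = c(0, 0))
  expect_equal(fit3$results$stat, 0)
  expect_equal(fit3$results$pvalue, 1)
})

test_that("dispersion estimator recovers planted phi and truncates at 0", {
  sim_group_counts <- function(phi, p = 0.3, nloci = 4000, reps = 3, cov = 40) {
    n <- matrix(rpois(nloci * reps, cov) + 10L, nloci)
    pr <- if (phi > 0) {
      matrix(rbeta(nloci * reps, p * (1 - phi) / phi, (1 - p) * (1 - phi) / phi), nloci)
    } else matrix(p, nloci, reps)
    x <- matrix(rbinom(nloci * reps, n, pr), nloci)
    tibble::tibble(contig = "c1", pos = rep(seq_len(nloci), reps),
                   strand = "+", replicate = rep(seq_len(reps), each = nloci),
                   count_m = as.vector(x), cov = as.vector(n))
  }
  set.seed(61)
  est0 <- replicate(5, estimate_dispersion(sim_group_counts(0)))
  expect_lt(mean(est0), 0.004) # truncated-at-0 estimates hug zero under binomial data

  est5 <- replicate(5, estimate_dispersion(sim_group_counts(0.05)))
  se <- sd(est5) / sqrt(5)
  expect_lt(abs(mean(est5) - 0.05), 3 * se + 0.003)

  single <- sim_group_counts(0)[1:10, ]
  single$replicate <- 1
  expect_warning(phi1 <- estimate_dispersion(single), "fewer than 2 replicates")
  expect_equal(phi1, 0)
})

test_that("empirical type-I error is calibrated at moderate methylation", {
  set.seed(71)
  nloci <- 20000
  simulate_null_fit <- function() {
    phi <- 0.02; p <- 0.3
    draw <- function(group) {
      n <- matrix(rnbinom(nloci * 3, mu = 30, size = 10), nloci); n[n < 10] <- 10
      pr <- matrix(rbeta(nloci * 3, p * (1 - phi) / phi, (1 - p) * (1 - phi) / phi), nloci)
      x <- matrix(rbinom(nloci * 3, n, pr), nloci)
      group_from_matrices(seq_len(nloci) * 50, x, n, group)
    }
    dml_test(draw("A"), draw("B"), config = dm_config(genic_only = FALSE))
  }
  fit <- simulate_null_fit()
  for (alpha in c(0.05, 0.01)) {
    frac <- mean(fit$results$pvalue < alpha)
    se <- sqrt(alpha * (1 - alpha) / nloci)
    expect_lt(abs(frac - alpha), 3 * se)
  }
})

test_that("power is non-decreasing in effect size and coverage", {
  set.seed(81)
  nloci <- 1500
  power_at <- function(delta, cov) {
    draw <- function(p, group) {
      n <- matrix(cov, nloci, 3)
      x <- matrix(rbinom(nloci * 3, cov, p), nloci)
      group_from_matrices(seq_len(nloci) * 50, x, n, group)
    }
    fit <- dml_test(draw(0.3, "A"), draw(0.3 + delta, "B"),
                    config = dm_config(genic_only = FALSE), dispersion = c(0, 0))
    mean(fit$results$pvalue < 0.05)
  }
  p_effect <- vapply(c(0, 0.1, 0.25), power_at, numeric(1), cov = 30)
  expect_true(all(diff(p_effect) > 0))
  p_cov <- vapply(c(10, 30, 60), function(cv) power_at(0.15, cv), numeric(1))
  expect_true(all(diff(p_cov) > 0))
})

test_that("DMR calling follows the greedy area-statistic procedure", {
  base <- tibble::tibble(contig = "c1", strand = "+",
                         mu1 = 0.5, mu2 = 0.2, diff = 0.3, se = 0.1)
  mk <- function(pos, stat, sig = TRUE) {
    dplyr::mutate(base[rep(1, length(pos)), ], pos = pos, stat = stat,
                  pvalue = ifelse(sig, 0.001, 0.5), padj = pvalue,
                  significant = sig, diff = sign(stat) * 0.3)
  }
  cfg <- dm_config(genic_only = FALSE)

  # no significant loci -> no regions
  expect_equal(nrow(call_dmr(mk(c(1, 60, 120), 1.2, sig = FALSE), cfg)), 0)

  # 5 consecutive significant loci within 40 bp (min span relaxed to match)
  cfg40 <- dm_config(genic_only = FALSE, min_length = 40)
  r <- call_dmr(mk(seq(10, 50, 10), c(3, 3, 4, 3, 3)), cfg40)
  expect_equal(nrow(r), 1)
  expect_equal(r$area_stat, 16)
  expect_equal(r$pct_sig, 1)
  expect_equal(c(r$start, r$end), c(10, 50))

  # two clusters split by a gap beyond merge_dist
  r2 <- call_dmr(mk(c(seq(10, 70, 20), seq(400, 460, 20)), 3), cfg)
  expect_equal(nrow(r2), 2)

  # opposing signs never share a region
  r3 <- call_dmr(mk(seq(10, 90, 20), c(3, 3, -3, -3, 3)), cfg)
  expect_true(all(r3$n_sig < 5))

  # regions failing min_sites / pct_sig / min_length are dropped
  two <- mk(c(10, 30), 3)
  expect_equal(nrow(call_dmr(two, cfg)), 0) # only 2 sites and 21 bp span
  diluted <- dplyr::bind_rows(mk(seq(10, 90, 40), 3),
                              mk(seq(20, 80, 10)[!seq(20, 80, 10) %in% seq(10, 90, 40)],
                                 0.5, sig = FALSE)) |> dplyr::arrange(pos)
  expect_equal(nrow(call_dmr(diluted, cfg)), 0) # 3/9 significant < 50 %

  # deterministic ordering by |area_stat| then coordinates
  r4 <- call_dmr(dplyr::bind_rows(mk(seq(1000, 1080, 20), 2), mk(seq(10, 90, 20), 5)), cfg)
  expect_equal(r4$start, c(10, 1000))
})

test_that("regions map to genes by >= 1 bp overlap", {
  ann <- feature_annotation(
    genes = tibble::tibble(gene_id = c("g1", "g2"), contig = "c1", strand = "+",
                           start = c(100L, 350L), end = c(400L, 600L)),
    exons = tibble::tibble(gene_id = c("g1", "g2"), contig = "c1",
                           start = c(100L, 350L), end = c(400L, 600L)),
    contig_lengths = c(c1 = 1000L))
  regions <- tibble::tibble(contig = "c1", start = c(150L, 380L, 700L),
                            end = c(200L, 390L, 720L), n_cg = 5L, n_sig = 5L,
                            pct_sig = 1, area_stat = c(10, 8, 6),
                            mean_diff = 0.3, direction = "hyper")
  dme <- map_regions_to_genes(regions, ann)
  expect_setequal(dme$gene_id, c("g1", "g2"))
  # the region at 380..390 overlaps both overlapping genes
  expect_equal(dme$n_regions[dme$gene_id == "g1"], 2)
  expect_equal(dme$area_stat_sum[dme$gene_id == "g1"], 18)
  # intergenic region (700..720) contributes nowhere
  expect_equal(sum(dme$n_regions), 3)
})
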