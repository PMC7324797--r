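test_that("read_fasta parses, upper-cases and joins lines, and rejects bad input", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT"), tf)
  expect_identical(read_fasta(tf), c(c1 = "ACGT"))

  writeLines(c(">c1", "acg", "tN"), tf)
  expect_identical(read_fasta(tf), c(c1 = "ACGTN"))

  writeLines(c(">c1", "ACGT", ">c1", "AA"), tf)
  expect_error(read_fasta(tf), "duplicate record id 'c1'")
  expect_error(read_fasta(tf), "line 3")

  writeLines(character(0), tf)
  expect_error(read_fasta(tf), "empty")

  writeLines(c(">c1", "ACXT"), tf)
  expect_error(read_fasta(tf), "illegal character")
})

test_that("FASTA write/read is an identity and wraps at 60 columns", {
  genome <- c(c1 = paste(rep("ACGTT", 30), collapse = ""), c2 = "ACGTN")
  tf <- withr::local_tempfile(fileext = ".fa")
  write_fasta(genome, tf)
  expect_identical(read_fasta(tf), genome)
  expect_true(all(nchar(readLines(tf)) <= 60))
})

test_that("read_gff3 assembles gene models and derives the feature partition", {
  genome <- c(c1 = paste(rep("A", 150), collapse = ""))
  tf <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
    "c1\tsrc\texon\t61\t100\t.\t+\t.\tParent=g1", # unsorted on purpose
    "c1\tsrc\texon\t1\t40\t.\t+\t.\tParent=g1"), tf)
  ann <- read_gff3(tf, genome)
  expect_equal(nrow(ann$genes), 1)
  expect_equal(nrow(ann$exons), 2)
  cls <- classify_position(ann, "c1", 1:150)
  expect_true(all(cls[1:40] == "exon"))
  expect_true(all(cls[41:60] == "intron"))
  expect_true(all(cls[61:100] == "exon"))
  expect_true(all(cls[101:150] == "intergenic"))

  # single exon spanning the gene: no intron positions
  writeLines(c(
    "##gff-version 3",
    "c1\tsrc\tgene\t10\t50\t.\t-\t.\tID=g1",
    "c1\tsrc\texon\t10\t50\t.\t-\t.\tParent=g1"), tf)
  ann2 <- read_gff3(tf, genome)
  expect_equal(sum(IRanges::width(ann2$intron_gr)), 0)

  # exon beyond the contig end
  writeLines(c(
    "##gff-version 3",
    "c1\tsrc\tgene\t80\t160\t.\t+\t.\tID=g1",
    "c1\tsrc\texon\t90\t160\t.\t+\t.\tParent=g1"), tf)
  expect_error(read_gff3(tf, genome), "out of contig bounds")

  # features on a contig the genome lacks
  writeLines(c(
    "##gff-version 3",
    "cX\tsrc\tgene\t1\t10\t.\t+\t.\tID=g1"), tf)
  expect_error(read_gff3(tf, genome), "absent from genome")
})

test_that("feature_annotation validates exon/gene consistency", {
  lens <- c(c1 = 200L)
  genes <- tibble::tibble(gene_id = "g1", contig = "c1", strand = "+",
                          start = 50L, end = 100L)
  bad_exon <- tibble::tibble(gene_id = "g1", contig = "c1", start = 40L, end = 60L)
  expect_error(feature_annotation(genes, bad_exon, lens), "outside its gene span")
  orphan <- tibble::tibble(gene_id = "gX", contig = "c1", start = 55L, end = 60L)
  expect_error(feature_annotation(genes, orphan, lens), "unresolvable")
  overlapping <- tibble::tibble(gene_id = c("g1", "g1"), contig = "c1",
                                start = c(50L, 58L), end = c(60L, 70L))
  expect_error(feature_annotation(genes, overlapping, lens), "overlapping exons")
})

test_that("classify_position applies exon > intron > intergenic precedence for overlapping genes", {
  # g2's exon covers 120..140; that span is intronic in g1
  ann <- feature_annotation(
    genes = tibble::tibble(gene_id = c("g1", "g2"), contig = "c1", strand = "+",
                           start = c(1L, 110L), end = c(200L, 150L)),
    exons = tibble::tibble(gene_id = c("g1", "g1", "g2"), contig = "c1",
                           start = c(1L, 180L, 120L), end = c(100L, 200L, 140L)),
    contig_lengths = c(c1 = 300L))
  expect_identical(classify_position(ann, "c1", 130L), "exon")
  expect_identical(classify_position(ann, "c1", 115L), "intron")
  expect_identical(classify_position(ann, "c1", 250L), "intergenic")
  expect_error(classify_position(ann, "c1", 301L), "out of contig range")
})

test_that("position partition covers every base exactly once", {
  set.seed(11)
  for (rep in 1:5) {
    cfg <- sim_config(seed = rep, contig_lengths = c(chr1 = 5000L),
                      n_genes = sample(0:4, 1), exons_per_gene = 2L,
                      exon_length = 150L, intron_length = 200L)
    genome <- simulate_genome(cfg)
    ann <- simulate_annotation(genome, cfg)
    cls <- classify_position(ann, "chr1", 1:5000)
    expect_equal(length(cls), 5000)
    counts <- table(factor(cls, c("exon", "intron", "intergenic")))
    expect_equal(sum(counts), 5000)
    expect_equal(unname(counts[["exon"]]), sum(IRanges::width(ann$exon_gr)))
    expect_equal(unname(counts[["intron"]]), sum(IRanges::width(ann$intron_gr)))
  }
})

test_that("nucleotide_frequencies matches hand counts and handles N and regions", {
  f <- nucleotide_frequencies(c(c1 = "ACGT"))
  expect_equal(kmer_freq(f, "C"), 0.25)
  expect_equal(kmer_freq(f, "G"), 0.25)
  expect_equal(kmer_freq(f, "CG"), 1 / 3)

  fn <- nucleotide_frequencies(c(c1 = "NNNN"))
  expect_true(all(is.nan(fn$freq)))

  # windows never span the gap between two regions
  f2 <- nucleotide_frequencies(c(c1 = "CGACGA"),
                               regions = tibble::tibble(contig = "c1",
                                                        start = c(1L, 4L),
                                                        end = c(2L, 5L)))
  expect_equal(kmer_freq(f2, "CG"), 1)

  expect_error(nucleotide_frequencies(c(c1 = "ACGT"),
                                      regions = tibble::tibble(contig = character(),
                                                               start = integer(),
                                                               end = integer())),
               "empty")
})

test_that("frequencies normalise within each k and agree with a sliding-window oracle", {
  set.seed(21)
  for (rep in 1:25) {
    s <- random_seq(1000, gc = runif(1, 0.25, 0.65), p_n = ifelse(rep %% 5 == 0, 0.02, 0))
    f <- nucleotide_frequencies(setNames(s, "c1"))
    for (k in 1:3) {
      fk <- f[f$k == k, ]
      expect_equal(sum(fk$freq), 1, tolerance = 1e-12)
      oracle <- oracle_kmer_counts(s, k)
      got <- setNames(fk$count, fk$kmer)[names(oracle)]
      expect_equal(unname(got), unname(oracle))
      expect_equal(sum(fk$count), sum(oracle))
    }
  }
})
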