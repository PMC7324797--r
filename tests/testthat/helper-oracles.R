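# Brute-force oracles and small construction helpers shared by the tests.

# random sequence over ACGT (optionally with N) as a single string
random_seq <- function(n, gc = 0.5, p_n = 0) {
  probs <- c((1 - gc) / 2 * (1 - p_n), gc / 2 * (1 - p_n),
             gc / 2 * (1 - p_n), (1 - gc) / 2 * (1 - p_n), p_n)
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# sliding-window k-mer counter, independent of Biostrings
oracle_kmer_counts <- function(seqs, k) {
  counts <- new.env()
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("N", w, fixed = TRUE)) next
      counts[[w]] <- (counts[[w]] %||% 0) + 1
    }
  }
  unlist(as.list(counts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# substring-based context classifier: looks at the two bases downstream of
# a cytosine on its own strand, using the reverse complement for minus
oracle_context <- function(seq, pos, strand) {
  if (strand == "-") {
    n <- nchar(seq)
    seq <- bsmethyl::revcomp(seq)
    pos <- n - pos + 1
  }
  stopifnot(substr(seq, pos, pos) == "C")
  b1 <- if (pos + 1 <= nchar(seq)) substr(seq, pos + 1, pos + 1) else "N"
  b2 <- if (pos + 2 <= nchar(seq)) substr(seq, pos + 2, pos + 2) else "N"
  if (b1 == "G") return("CpG")
  if (b1 == "N") return("UNDEFINED")
  if (b2 == "G") return("CHG")
  if (b2 == "N") return("UNDEFINED")
  "CHH"
}

# one-contig methylome from parallel count vectors (CpG, plus strand)
counts_sample <- function(pos, m, cov, context = "CpG", strand = "+",
                          group = NA_character_, replicate = NA_integer_) {
  methylome_sample(
    tibble::tibble(contig = "c1", pos = as.integer(pos), strand = strand,
                   count_m = as.integer(m), count_u = as.integer(cov - m),
                   context = context, trinucleotide = "CGA"),
    sample_id = paste0(group, "_", replicate), group = group, replicate = replicate)
}

# analytic standard error of a pooled call-weighted percent under the
# simulator's beta-binomial model, from the realized per-site-replicate
# coverages (pp scale)
pooled_percent_se <- function(p, coverages, phi) {
  v <- p * (1 - p) * sum(coverages * (1 + (coverages - 1) * phi)) / sum(coverages)^2
  100 * sqrt(v)
}

# tiny two-gene annotation on a 150 bp contig used across io tests
toy_annotation <- function() {
  feature_annotation(
    genes = tibble::tibble(gene_id = "g1", contig = "c1", strand = "+",
                           start = 1L, end = 100L),
    exons = tibble::tibble(gene_id = c("g1", "g1"), contig = "c1",
                           start = c(1L, 61L), end = c(40L, 100L)),
    contig_lengths = c(c1 = 150L))
}
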