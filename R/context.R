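# Cytosine context classification (CpG / CHG / CHH) and observed/expected
# context-depletion ratios.

.CTX_LEVELS <- c("CpG", "CHG", "CHH", "UNDEFINED")

# character lookup by raw byte value
.BYTE_CHAR <- local({
  x <- rep("N", 256)
  x[as.integer(charToRaw("ACGTN")) + 1L] <- c("A", "C", "G", "T", "N")
  x
})

# core vectorised classifier: b1, b2 are the two bases downstream of the
# cytosine, 5'->3' on the cytosine's own strand (raw vectors; N for padding)
.context_core <- function(b1, b2) {
  ctx <- rep("UNDEFINED", length(b1))
  h1 <- b1 == .BASE_A | b1 == .BASE_C | b1 == .BASE_T
  ctx[b1 == .BASE_G] <- "CpG"
  ctx[h1 & b2 == .BASE_G] <- "CHG"
  ctx[h1 & (b2 == .BASE_A | b2 == .BASE_C | b2 == .BASE_T)] <- "CHH"
  ctx
}

# downstream bases for positions idx on one contig (raw vector b)
.downstream <- function(b, idx, strand) {
  n <- length(b)
  if (strand == "+") {
    pad <- c(b, .BASE_N, .BASE_N)
    list(b1 = pad[idx + 1L], b2 = pad[idx + 2L])
  } else {
    pad <- c(.BASE_N, .BASE_N, b) # original position j sits at pad[j + 2]
    list(b1 = complement_raw(pad[idx + 1L]), b2 = complement_raw(pad[idx]))
  }
}

#' Classify the methylation context of cytosines
#'
#' Reading 5'->3' on the cytosine's own strand, the next base decides CpG
#' (next base G); otherwise the base after next decides CHG (G) versus CHH
#' (A/C/T). An N among the deciding bases, or a contig edge, yields
#' "UNDEFINED" (except that a C followed directly by G is CpG regardless of
#' the second base). A minus-strand cytosine sits at a plus-strand G.
#'
#' @param genome Named character vector of sequences.
#' @param contig Character vector of contig ids (recycled).
#' @param pos Integer vector of 1-based positions.
#' @param strand Character vector in \{"+","-"\} (recycled).
#' @return Character vector in \{"CpG","CHG","CHH","UNDEFINED"\}.
#' @export
#' @examples
#' classify_context(c(c1 = "ACGT"), "c1", 2, "+")
classify_context <- function(genome, contig, pos, strand) {
  check_genome(genome)
  n <- max(length(contig), length(pos), length(strand))
  contig <- rep_len(contig, n); pos <- rep_len(pos, n); strand <- rep_len(strand, n)
  if (!all(strand %in% c("+", "-"))) abort("`strand` must be '+' or '-'")
  lens <- contig_lengths(genome)
  if (any(!contig %in% names(lens))) abort("unknown contig")
  if (any(pos < 1 | pos > lens[contig])) abort("position out of contig range")
  out <- character(n)
  for (ct in unique(contig)) {
    b <- seq_to_raw(genome[[ct]])
    for (sd in c("+", "-")) {
      sel <- which(contig == ct & strand == sd)
      if (!length(sel)) next
      idx <- pos[sel]
      base <- b[idx]
      want <- if (sd == "+") .BASE_C else .BASE_G
      if (any(base != want)) {
        abort(sprintf("base at %s:%d(%s) is not a cytosine on that strand",
                      ct, idx[base != want][1], sd))
      }
      ds <- .downstream(b, idx, sd)
      out[sel] <- .context_core(ds$b1, ds$b2)
    }
  }
  out
}

#' Enumerate every cytosine of a genome with context and trinucleotide
#'
#' Emits every plus-strand C and every minus-strand C (a plus-strand G)
#' exactly once, sorted by contig, position, then strand (+ before -).
#' Trinucleotides are reported 5'->3' on the cytosine's strand, padded with
#' N at contig edges.
#'
#' @param genome Named character vector of sequences.
#' @return Tibble with columns `contig`, `pos` (1-based), `strand`,
#'   `context`, `trinucleotide`.
#' @export
#' @examples
#' enumerate_cytosines(c(c1 = "CG"))
enumerate_cytosines <- function(genome) {
  check_genome(genome)
  empty <- tibble(contig = character(), pos = integer(), strand = character(),
                  context = character(), trinucleotide = character())
  bind_rows(empty, purrr::map_dfr(names(genome), function(ct) {
    b <- seq_to_raw(genome[[ct]])
    res <- purrr::map_dfr(c("+", "-"), function(sd) {
      idx <- if (sd == "+") which(b == .BASE_C) else which(b == .BASE_G)
      if (!length(idx)) return(empty)
      ds <- .downstream(b, idx, sd)
      tibble(contig = ct, pos = idx, strand = sd,
             context = .context_core(ds$b1, ds$b2),
             trinucleotide = paste0("C",
                                    .BYTE_CHAR[as.integer(ds$b1) + 1L],
                                    .BYTE_CHAR[as.integer(ds$b2) + 1L]))
    })
    arrange(res, .data$pos, .data$strand)
  }))
}

# ratio with undefined-flagging
.oe_ratio <- function(num, den) {
  if (!is.finite(den) || den <= 0) return(NA_real_)
  num / den
}

#' CpG observed/expected ratio
#'
#' `F_CpG / (F_C * F_G)`: the observed CpG dinucleotide frequency relative
#' to its expectation under base independence. Values below 1 indicate CpG
#' depletion, the classic footprint of germline CpG methylation.
#'
#' @param freq A frequency table from [nucleotide_frequencies()].
#' @return A single ratio; `NA` (undefined) when the denominator is 0.
#' @export
oe_cpg <- function(freq) {
  .oe_ratio(kmer_freq(freq, "CG"),
            kmer_freq(freq, "C") * kmer_freq(freq, "G"))
}

#' CHG observed/expected ratio
#'
#' `(F_CAG + F_CTG + F_CCG) / (3 * F_C * F_H * F_G)`, where `F_H =
#' (1 - F_G) / 3` is the average frequency of a single non-G base (the H
#' slot of C-H-G). The factor 3 in the denominator counts the three H
#' choices, so the expression simplifies to
#' `sum(F_CHG) / (F_C * (1 - F_G) * F_G)` and, like the CpG ratio,
#' converges to 1 on sequences with independent bases.
#'
#' @inheritParams oe_cpg
#' @return A single ratio; `NA` when the denominator is 0.
#' @export
oe_chg <- function(freq) {
  fc <- kmer_freq(freq, "C"); fg <- kmer_freq(freq, "G")
  fh <- (1 - fg) / 3
  .oe_ratio(sum(kmer_freq(freq, c("CAG", "CTG", "CCG"))),
            3 * fc * fh * fg)
}

#' CHH observed/expected ratio
#'
#' Sum of the nine C-H-H trinucleotide frequencies (H in \{A,C,T\}) over
#' `9 * F_C * F_H^2`, with `F_H = (1 - F_G) / 3` the average single-H
#' frequency; the factor 9 counts the H pairs, so the expression
#' simplifies to `sum(F_CHH) / (F_C * (1 - F_G)^2)` and converges to 1 on
#' sequences with independent bases.
#'
#' @inheritParams oe_cpg
#' @return A single ratio; `NA` when the denominator is 0.
#' @export
oe_chh <- function(freq) {
  h <- c("A", "C", "T")
  tri <- paste0("C", rep(h, each = 3), rep(h, 3))
  fc <- kmer_freq(freq, "C"); fg <- kmer_freq(freq, "G")
  fh <- (1 - fg) / 3
  .oe_ratio(sum(kmer_freq(freq, tri)), 9 * fc * fh^2)
}

#' All three O/E ratios of one frequency table
#'
#' @inheritParams oe_cpg
#' @param label Optional region label for the output row.
#' @return One-row tibble: `region_class`, `n_windows` (valid trinucleotide
#'   windows), `cpg_oe`, `chg_oe`, `chh_oe`.
#' @export
oe_ratios <- function(freq, label = "genome") {
  tibble(region_class = label,
         n_windows = sum(freq$count[freq$k == 3]),
         cpg_oe = oe_cpg(freq), chg_oe = oe_chg(freq), chh_oe = oe_chh(freq))
}

#' O/E profile across feature classes
#'
#' Computes the three observed/expected ratios for each region class,
#' pooling k-mer counts across all regions of a class before forming the
#' ratios. Empty classes are flagged with `NA` ratios.
#'
#' @param genome Named character vector of sequences.
#' @param annotation A [feature_annotation].
#' @param classes Character vector of classes to profile.
#' @return Tibble with one row per class, as [oe_ratios()].
#' @export
oe_profile <- function(genome, annotation,
                       classes = c("genome", "genic", "intergenic", "exon", "intron")) {
  check_genome(genome)
  stopifnot(inherits(annotation, "feature_annotation"))
  purrr::map_dfr(classes, function(cl) {
    regions <- feature_regions(annotation, cl)
    if (nrow(regions) == 0) {
      return(tibble(region_class = cl, n_windows = 0,
                    cpg_oe = NA_real_, chg_oe = NA_real_, chh_oe = NA_real_))
    }
    oe_ratios(nucleotide_frequencies(genome, regions), label = cl)
  })
}
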