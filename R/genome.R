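#' Read a genome from a FASTA file
#'
#' Wraps [Biostrings::readDNAStringSet()] and returns the genome as a named
#' character vector of upper-case sequences over the alphabet \{A,C,G,T,N\}.
#' Lower-case input is folded to upper case; multi-line records are
#' concatenated. Duplicate record ids, characters outside the alphabet and
#' empty files are reported as format errors, with the offending line number
#' where it can be located.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector: contig id -> sequence.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgT"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  if (file.size(path) == 0) abort(sprintf("FASTA format error in %s: file is empty", path))
  set <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path),
      error = function(e) abort(sprintf("FASTA format error in %s: %s", path, conditionMessage(e)))
    ),
    warning = function(w) {
      # Biostrings silently drops invalid letters with a warning; treat as error
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        abort(sprintf("FASTA format error in %s (line %d): illegal character",
                      path, .fasta_first_bad_line(path)))
      }
      invokeRestart("muffleWarning")
    }
  )
  if (length(set) == 0) abort(sprintf("FASTA format error in %s: no records", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    line <- .fasta_line_of_header(path, dup, occurrence = 2L)
    abort(sprintf("FASTA format error in %s (line %d): duplicate record id '%s'", path, line, dup))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    id <- ids[bad][1]
    line <- .fasta_line_of_bad_char(path, id)
    abort(sprintf("FASTA format error in %s (line %d): illegal character in record '%s'", path, line, id))
  }
  if (any(nchar(seqs) < 1L)) {
    id <- ids[nchar(seqs) < 1L][1]
    abort(sprintf("FASTA format error in %s: record '%s' has an empty sequence", path, id))
  }
  seqs
}

# locate the n-th header line for a given id (diagnostics only)
.fasta_line_of_header <- function(path, id, occurrence = 1L) {
  lines <- readLines(path, warn = FALSE)
  hit <- which(sub("\\s.*$", "", sub("^>", "", lines)) == id & startsWith(lines, ">"))
  if (length(hit) >= occurrence) hit[occurrence] else NA_integer_
}

.fasta_first_bad_line <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    if (!startsWith(lines[i], ">") && grepl("[^ACGTNacgtn]", lines[i])) return(i)
  }
  NA_integer_
}

.fasta_line_of_bad_char <- function(path, id) {
  lines <- readLines(path, warn = FALSE)
  headers <- which(startsWith(lines, ">"))
  start <- headers[sub("\\s.*$", "", sub("^>", "", lines[headers])) == id][1]
  stop_at <- c(headers[headers > start], length(lines) + 1L)[1] - 1L
  for (i in seq(start + 1L, stop_at)) {
    if (grepl("[^ACGTNacgtn]", lines[i])) return(i)
  }
  NA_integer_
}

#' Write a genome to a FASTA file
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  check_genome(genome)
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Mono-, di- and trinucleotide frequencies of a genome or region set
#'
#' Counts overlapping k-mer windows (k = 1, 2, 3) on the plus strand of the
#' supplied genome, optionally restricted to a set of regions. Windows are
#' counted per contiguous region, so no window spans a region boundary, and
#' counts are summed over regions before normalising. Windows containing N
#' are excluded from both numerator and denominator (a property of
#' [Biostrings::oligonucleotideFrequency()], which only bins windows over
#' the standard alphabet).
#'
#' @param genome Named character vector of sequences.
#' @param regions Optional tibble/data.frame with columns `contig`, `start`,
#'   `end` (1-based inclusive). When `NULL`, the whole genome is used.
#' @return A tibble with columns `kmer`, `k`, `count`, `freq`, where `freq`
#'   normalises counts within each k. When no valid window exists for a k
#'   (e.g. an all-N region), the frequencies for that k are `NaN`.
#' @export
#' @examples
#' nucleotide_frequencies(c(c1 = "ACGT"))
nucleotide_frequencies <- function(genome, regions = NULL) {
  check_genome(genome)
  if (!is.null(regions)) {
    regions <- as_tibble(regions)
    if (nrow(regions) == 0) abort("`regions` is empty.")
    stopifnot(all(c("contig", "start", "end") %in% names(regions)))
    lens <- contig_lengths(genome)
    unknown <- setdiff(unique(regions$contig), names(genome))
    if (length(unknown)) abort(sprintf("regions on unknown contig(s): %s", paste(unknown, collapse = ", ")))
    if (any(regions$start < 1 | regions$end > lens[regions$contig] | regions$end < regions$start)) {
      abort("region coordinates out of contig bounds")
    }
    seqs <- substr(genome[regions$contig], regions$start, regions$end)
  } else {
    seqs <- unname(genome)
  }
  set <- Biostrings::DNAStringSet(seqs)
  purrr::map_dfr(1:3, function(k) {
    cnt <- colSums(Biostrings::oligonucleotideFrequency(set, width = k, step = 1L))
    tibble(kmer = names(cnt), k = k, count = as.numeric(cnt),
           freq = as.numeric(cnt) / sum(cnt))
  })
}

#' Look up k-mer frequencies in a frequency table
#'
#' @param freq A tibble from [nucleotide_frequencies()].
#' @param kmers Character vector of k-mers (all of one length).
#' @return Numeric vector of frequencies (0 for absent k-mers of a present k).
#' @export
kmer_freq <- function(freq, kmers) {
  idx <- match(kmers, freq$kmer)
  if (anyNA(idx)) abort(sprintf("unknown k-mer(s): %s", paste(kmers[is.na(idx)], collapse = ", ")))
  freq$freq[idx]
}
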