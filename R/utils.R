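# Internal helpers. Sequences are handled as raw vectors (one byte per base)
# in hot paths; conversion helpers live here so the rest of the package can
# stay on plain character strings.

.BASE_A <- as.raw(65L) # "A"
.BASE_C <- as.raw(67L) # "C"
.BASE_G <- as.raw(71L) # "G"
.BASE_T <- as.raw(84L) # "T"
.BASE_N <- as.raw(78L) # "N"

seq_to_raw <- function(x) charToRaw(x)

raw_to_seq <- function(x) rawToChar(x)

# complement of a raw base vector; N stays N
complement_raw <- function(b) {
  out <- rep(.BASE_N, length(b))
  out[b == .BASE_A] <- .BASE_T
  out[b == .BASE_T] <- .BASE_A
  out[b == .BASE_C] <- .BASE_G
  out[b == .BASE_G] <- .BASE_C
  out
}

#' Reverse-complement a nucleotide string
#'
#' Upper-case A/C/G/T are complemented, any other letter becomes N.
#'
#' @param x A character vector of nucleotide strings.
#' @return A character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  vapply(x, function(s) raw_to_seq(rev(complement_raw(seq_to_raw(s)))),
         character(1), USE.NAMES = FALSE)
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in seq_along(idx)) s <- (s * 7919 + as.double(idx[i]) * 104729) %% 2147483647
  as.integer(s) + 1L
}

# validate a genome object: named character vector over {A,C,G,T,N}
check_genome <- function(genome, arg = "genome") {
  if (!is.character(genome) || is.null(names(genome)) ||
      any(!nzchar(names(genome))) || anyDuplicated(names(genome))) {
    abort(sprintf("`%s` must be a named character vector with unique, non-empty contig ids.", arg))
  }
  if (any(nchar(genome) < 1L)) abort(sprintf("`%s` contains an empty sequence.", arg))
  bad <- grepl("[^ACGTN]", genome)
  if (any(bad)) {
    abort(sprintf("`%s` contains characters outside {A,C,G,T,N} in contig(s): %s",
                  arg, paste(names(genome)[bad], collapse = ", ")))
  }
  invisible(genome)
}

contig_lengths <- function(genome) {
  setNames(nchar(genome), names(genome))
}

# percent with undefined-flagging: returns NA_real_ when total == 0
percent_of <- function(meth, total) {
  ifelse(total > 0, 100 * meth / total, NA_real_)
}
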