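# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# Reverse-complement a character vector of DNA strings.
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

complement_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

# Vectorised single-base lookup on a genome string; pos is 0-based.
# Out-of-range positions return NA.
base_at <- function(seq_string, pos) {
  out <- rep(NA_character_, length(pos))
  ok <- !is.na(pos) & pos >= 0L & pos < nchar(seq_string)
  if (any(ok)) out[ok] <- substring(seq_string, pos[ok] + 1L, pos[ok] + 1L)
  out
}

# Extract [lo, hi) 0-based half-open substrings from a genome string.
span_at <- function(seq_string, lo, hi) {
  substring(seq_string, lo + 1L, hi)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Map a transcript-orientation offset (no 0; -1 = 3' end base) to a
# 0-based genomic coordinate, given the 3'-end coordinate and strand.
offset_to_genomic <- function(pos3, strand, offset) {
  stopifnot(all(offset != 0L))
  n <- max(length(pos3), length(strand), length(offset))
  pos3 <- rep_len(pos3, n); strand <- rep_len(strand, n)
  offset <- rep_len(offset, n)
  shift <- ifelse(offset < 0L, offset + 1L, offset)
  ifelse(strand == "+", pos3 + shift, pos3 - shift)
}

# Base composition of a genome string as named fractions over A/C/G/T.
base_composition <- function(seq_string) {
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(seq_string), BASES)
  counts / sum(counts)
}
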