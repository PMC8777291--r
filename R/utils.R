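# Internal sequence and misc helpers.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Reverse complement of a DNA character vector (uppercase A/C/G/T/N).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Translate an in-frame DNA string (length divisible by 3) with the standard
# genetic code; stops become "*".
translate_dna <- function(x) {
  n <- nchar(x)
  if (n == 0L) return("")
  stopifnot(n %% 3 == 0L)
  codons <- substring(x, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

split_codons <- function(x) {
  n <- nchar(x)
  substring(x, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

check_dna_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside A/C/G/T/N", what),
          class = "circpept_sequence_error")
  }
  invisible(x)
}

# Derive a reproducible per-stage seed from the master seed, kept < 2^31.
stage_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7L + k * 1013L) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
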