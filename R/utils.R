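# Internal sequence helpers. All coordinates in this package are 0-based,
# half-open [start, end) on the plus strand unless a function documents
# otherwise; conversion to 1-based closed coordinates happens only in the
# I/O layer.

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @importFrom rlang abort warn
NULL

# substring by 0-based half-open interval
subseq0 <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

# remove [start, end) from seq
splice0 <- function(seq, start, end) {
  paste0(substr(seq, 1L, start), substr(seq, end + 1L, nchar(seq)))
}

# replace [start, end) of seq with replacement
replace0 <- function(seq, start, end, replacement) {
  paste0(substr(seq, 1L, start), replacement, substr(seq, end + 1L, nchar(seq)))
}

# insert at position pos (before the base currently at 0-based index pos)
insert0 <- function(seq, pos, insertion) {
  paste0(substr(seq, 1L, pos), insertion, substr(seq, pos + 1L, nchar(seq)))
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# vector of single characters -> positions differing between two equal-length
# strings (0-based); errors if lengths differ
hamming_positions <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  which(charToRaw(a) != charToRaw(b)) - 1L
}

hamming_distance <- function(a, b) {
  length(hamming_positions(a, b))
}

assert_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    abort(sprintf("%s must be a single character string", what))
  }
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), DNA_BASES)
  if (length(bad) > 0) {
    abort(sprintf("%s contains non-ACGT characters: %s", what,
                  paste(bad, collapse = ", ")))
  }
  invisible(seq)
}

assert_iupac <- function(pattern, what = "pattern") {
  bad <- setdiff(unique(strsplit(pattern, "")[[1]]),
                 names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad) > 0) {
    abort(sprintf("%s contains invalid IUPAC codes: %s", what,
                  paste(bad, collapse = ", ")))
  }
  invisible(pattern)
}

# run expr under a private RNG stream without disturbing the caller's RNG;
# seed = NULL uses (and advances) the caller's stream
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
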