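BASES <- c("A", "C", "G", "T")

# the 12 template>read substitution classes, transcript space, U written as T
SUBSTITUTIONS <- as.vector(outer(BASES, BASES, function(x, y) paste0(x, ">", y)))[
  as.vector(outer(BASES, BASES, `!=`))
]

#' Reverse complement of DNA strings
#'
#' Vectorised over a character vector; N maps to N.
#' @param x character vector of A/C/G/T/N strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

complement_chr <- function(x) chartr("ACGTN", "TGCAN", x)

# deterministic per-stage seed derived from one run seed; stays below 2^31
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# decode a Phred+33 quality string into integer scores
phred_decode <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

# encode integer scores as one Phred+33 string each; a bare integer vector
# encodes to a single string
phred_encode <- function(scores) {
  if (!is.list(scores)) scores <- list(scores)
  vapply(scores, function(s) intToUtf8(s + 33L), character(1))
}

#' Base-call accuracy implied by a Phred score
#'
#' Phred Q is -10 log10 of the base-call error probability, so Q30
#' corresponds to 99.9% accuracy.
#'
#' @param q Phred score(s).
#' @return accuracy in percent.
#' @export
phred_to_accuracy <- function(q) 100 * (1 - 10^(-q / 10))

# fast per-base view of a set of reads: one row per (read, base)
# returns list(read = integer index, pos = 1-based position within read,
#              flat = index into the concatenated character vector)
flat_index <- function(lens) {
  list(
    read = rep.int(seq_along(lens), lens),
    pos = sequence(lens),
    starts = cumsum(c(0L, lens[-length(lens)])) + 1L
  )
}

stopifnot_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
}
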