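# Internal string-level sequence helpers. Sequences are plain uppercase
# character scalars over {A,C,G,T,N}; Biostrings objects appear only at the
# file-format boundary.

CANONICAL_BASES <- c("A", "C", "G", "T", "N")

#' Canonicalize a nucleotide string
#'
#' Uppercases, maps U to T and any other IUPAC/unknown character to N.
#'
#' @param seq Character scalar.
#' @param warn Warn when non-canonical characters are replaced by N.
#' @return Canonical character scalar over A/C/G/T/N.
#' @export
canonicalize_seq <- function(seq, warn = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("u", "t", toupper(seq))
  s <- chartr("U", "T", s)
  bad <- gsub("[ACGTN]", "", s)
  if (nzchar(bad)) {
    if (warn) {
      warning(sprintf("%d non-ACGTN character(s) mapped to N", nchar(bad)))
    }
    s <- gsub("[^ACGTN]", "N", s)
  }
  s
}

#' Reverse complement of a nucleotide string
#'
#' N maps to N; input must be canonical (see [canonicalize_seq()]).
#'
#' @param seq Character scalar over A/C/G/T/N.
#' @return Reverse complement, same alphabet.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# character vector <-> string
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]
chars_seq <- function(x) paste(x, collapse = "")

comp_chars <- function(x) chartr("ACGTN", "TGCAN", x)

# longest common prefix length of two strings (byte-wise)
lcp_len <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  m <- min(length(ra), length(rb))
  if (m == 0L) return(0L)
  d <- which(ra[seq_len(m)] != rb[seq_len(m)])
  if (length(d) == 0L) m else d[1L] - 1L
}

# longest common suffix length of two strings
lcs_len <- function(a, b) {
  ra <- rev(charToRaw(a)); rb <- rev(charToRaw(b))
  m <- min(length(ra), length(rb))
  if (m == 0L) return(0L)
  d <- which(ra[seq_len(m)] != rb[seq_len(m)])
  if (length(d) == 0L) m else d[1L] - 1L
}

# Hamming distance between equal-length strings
hamming <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

# random DNA string at a target GC fraction
random_dna <- function(n, gc_fraction = 0.5) {
  stopifnot(n >= 0, gc_fraction >= 0, gc_fraction <= 1)
  if (n == 0L) return("")
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  chars_seq(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p))
}

# replace substring [start, end] (1-based inclusive) of seq with repl
splice_seq <- function(seq, start, end, repl) {
  n <- nchar(seq)
  stopifnot(start >= 1L, end <= n, start <= end + 1L)
  paste0(substr(seq, 1L, start - 1L), repl, substr(seq, end + 1L, n))
}

# round half up at `digits` decimals (so 32.559 kb prints as 32.6 kb)
round_half_up <- function(x, digits = 0L) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}
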