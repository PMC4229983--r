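#' Mutational mechanism categories
#'
#' The five mechanism calls used throughout the package, in classifier
#' precedence order: SVA insertion-associated deletion, Alu-mediated
#' nonallelic homologous recombination (with MMEJ/replication-based
#' ambiguity), microhomology-mediated end joining / replication-based,
#' NHEJ with replication-based evidence, and plain non-homologous end
#' joining.
#'
#' @export
mechanism_levels <- c("NHEJ", "NHEJ_RBM", "MMEJ_RBM",
                      "ALU_NAHR_MMEJ_RBM", "SVA_INSERTION")

#' Validate a mechanism call
#'
#' @param value Character scalar; must be one of [mechanism_levels].
#' @return The validated value, invisibly usable as an enum.
#' @export
mechanism_call <- function(value) {
  if (!(is.character(value) && length(value) == 1L &&
        value %in% mechanism_levels)) {
    stop("mechanism must be one of: ", paste(mechanism_levels, collapse = ", "))
  }
  value
}

#' Genomic interval (1-based, inclusive)
#'
#' Coordinates are 1-based inclusive throughout the package; conversion to
#' 0-based half-open happens only when writing BED.
#'
#' @param contig Contig/sequence identifier.
#' @param start,end 1-based inclusive positions, `end >= start >= 1`.
#' @param strand One of "+", "-", "*" (unspecified).
#' @return A one-row data frame with class `genomic_interval`.
#' @export
genomic_interval <- function(contig, start, end, strand = "*") {
  stopifnot(length(contig) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    stop("invalid interval: need 1 <= start <= end")
  }
  if (!strand %in% c("+", "-", "*")) stop("strand must be +, - or *")
  out <- data.frame(contig = as.character(contig), start = start, end = end,
                    strand = strand, stringsAsFactors = FALSE)
  class(out) <- c("genomic_interval", class(out))
  out
}

#' Length of a 1-based inclusive interval
#'
#' @param start,end Positions, vectorized.
#' @return `end - start + 1`.
#' @export
interval_length <- function(start, end) {
  as.numeric(end) - as.numeric(start) + 1
}

#' Sequence record
#'
#' A named nucleotide sequence in canonical A/C/G/T/N uppercase form.
#'
#' @param id Record identifier (non-empty).
#' @param seq Nucleotide string; canonicalized on construction.
#' @return A list with class `sequence_record` (fields `id`, `seq`).
#' @export
sequence_record <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- canonicalize_seq(seq)
  if (!nzchar(seq)) stop("empty sequence for record '", id, "'")
  structure(list(id = id, seq = seq), class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s (%d bp)\n", x$id, nchar(x$seq)))
  invisible(x)
}

#' Deletion record
#'
#' One deletion with the feature fields of the study's per-patient table:
#' breakpoint coordinates, microhomology, insertion, single nucleotide
#' change and mosaicism flags, locus labels, SINE pair annotation and an
#' optional mechanism label.
#'
#' @param patient_id Patient identifier.
#' @param proximal_bp,distal_bp 1-based positions of the first and last
#'   deleted base (`distal_bp >= proximal_bp`).
#' @param microhomology_len Breakpoint microhomology in bp, or `NA` if none.
#' @param insertion_seq Nucleotide microinsertion at the junction, or `NA`.
#' @param insertion_templated Logical; insertion homologous to nearby flank
#'   sequence.
#' @param sva_family SVA subfamily label when the breakpoint carries an SVA
#'   insertion, else `NA`.
#' @param snc_present,mosaic Logical flags.
#' @param proximal_locus_label,distal_locus_label Gene/locus labels.
#' @param sine_pair Optional list with `name_proximal`, `name_distal`,
#'   `identity_percent` (0-100), `alignment_len_bp`.
#' @param mechanism_label Optional [mechanism_call()] value.
#' @return A list with class `deletion_record`; `$size` is derived as
#'   `distal_bp - proximal_bp + 1`.
#' @export
deletion_record <- function(patient_id, proximal_bp, distal_bp,
                            microhomology_len = NA_integer_,
                            insertion_seq = NA_character_,
                            insertion_templated = FALSE,
                            sva_family = NA_character_,
                            snc_present = FALSE, mosaic = FALSE,
                            proximal_locus_label = NA_character_,
                            distal_locus_label = NA_character_,
                            sine_pair = NULL,
                            mechanism_label = NA_character_) {
  proximal_bp <- as.numeric(proximal_bp); distal_bp <- as.numeric(distal_bp)
  if (is.na(proximal_bp) || is.na(distal_bp) || distal_bp < proximal_bp) {
    stop("deletion_record '", patient_id, "': need distal_bp >= proximal_bp")
  }
  if (!is.na(microhomology_len) && microhomology_len < 0) {
    stop("microhomology_len must be >= 0")
  }
  if (!is.null(sine_pair)) {
    stopifnot(sine_pair$identity_percent >= 0, sine_pair$identity_percent <= 100)
  }
  if (!is.na(mechanism_label)) mechanism_label <- mechanism_call(mechanism_label)
  structure(list(
    patient_id = patient_id,
    proximal_bp = proximal_bp, distal_bp = distal_bp,
    size = interval_length(proximal_bp, distal_bp),
    microhomology_len = microhomology_len,
    insertion_seq = insertion_seq,
    insertion_templated = isTRUE(insertion_templated),
    sva_family = sva_family,
    snc_present = isTRUE(snc_present), mosaic = isTRUE(mosaic),
    proximal_locus_label = proximal_locus_label,
    distal_locus_label = distal_locus_label,
    sine_pair = sine_pair,
    mechanism_label = mechanism_label
  ), class = "deletion_record")
}

#' Junction feature vector for mechanism classification
#'
#' @param mh_len Microhomology length in bp (0 if none).
#' @param insertion_len Microinsertion length in bp (0 if none).
#' @param insertion_templated Logical; insertion has a templated source near
#'   a breakpoint.
#' @param snc_present Logical; breakpoint-flanking single nucleotide change.
#' @param sva_detected Logical; SVA element detected at the junction.
#' @param sine_pair Optional list(identity_percent, alignment_len_bp,
#'   orientation) for repeats spanning both breakpoints; orientation is
#'   "direct" or "inverted".
#' @return A list with class `feature_vector`.
#' @export
feature_vector <- function(mh_len = 0L, insertion_len = 0L,
                           insertion_templated = FALSE, snc_present = FALSE,
                           sva_detected = FALSE, sine_pair = NULL) {
  mh_len <- as.integer(mh_len); insertion_len <- as.integer(insertion_len)
  stopifnot(!is.na(mh_len), mh_len >= 0L, !is.na(insertion_len),
            insertion_len >= 0L)
  if (!is.null(sine_pair)) {
    stopifnot(sine_pair$identity_percent >= 0,
              sine_pair$identity_percent <= 100)
    if (is.null(sine_pair$orientation)) sine_pair$orientation <- "direct"
  }
  structure(list(mh_len = mh_len, insertion_len = insertion_len,
                 insertion_templated = isTRUE(insertion_templated),
                 snc_present = isTRUE(snc_present),
                 sva_detected = isTRUE(sva_detected),
                 sine_pair = sine_pair), class = "feature_vector")
}
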