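# Mutational-mechanism classification from junction features. Precedence
# (first matching rule wins):
#   1. SVA element detected              -> SVA_INSERTION
#   2. microhomology >= 6 bp inside a directly oriented SINE pair with
#      >= 75% identity over >= 100 bp    -> ALU_NAHR_MMEJ_RBM
#   3. microhomology >= 6 bp             -> MMEJ_RBM
#   4. templated 1-11 bp insertion, or a breakpoint-flanking SNC
#                                        -> NHEJ_RBM
#   5. otherwise                         -> NHEJ
# Microhomology above 5 bp is the prerequisite for microhomology-mediated
# end joining; short (0-4 bp) microhomology is compatible with NHEJ, and
# templated microinsertions / flanking SNCs evidence replication-based
# template switching.

#' Default classifier thresholds
#'
#' @return Named list: `mmej_min_mh` (6 bp), `alu_min_identity` (75%),
#'   `alu_min_len` (100 bp), `max_templated_ins` (11 bp).
#' @export
classifier_thresholds <- function() {
  list(mmej_min_mh = 6L, alu_min_identity = 75, alu_min_len = 100L,
       max_templated_ins = 11L)
}

#' Classify one junction feature vector
#'
#' @param fv A [feature_vector()].
#' @param thresholds Threshold list (see [classifier_thresholds()]).
#' @return A mechanism string (one of [mechanism_levels]).
#' @export
classify_mechanism <- function(fv, thresholds = classifier_thresholds()) {
  stopifnot(inherits(fv, "feature_vector"))
  th <- utils::modifyList(classifier_thresholds(), thresholds)
  if (fv$sva_detected) return("SVA_INSERTION")
  sine_ok <- !is.null(fv$sine_pair) &&
    fv$sine_pair$identity_percent >= th$alu_min_identity &&
    fv$sine_pair$alignment_len_bp >= th$alu_min_len &&
    identical(fv$sine_pair$orientation, "direct")
  if (fv$mh_len >= th$mmej_min_mh && sine_ok) return("ALU_NAHR_MMEJ_RBM")
  if (fv$mh_len >= th$mmej_min_mh) return("MMEJ_RBM")
  if ((fv$insertion_len >= 1L && fv$insertion_len <= th$max_templated_ins &&
       fv$insertion_templated) || fv$snc_present) {
    return("NHEJ_RBM")
  }
  "NHEJ"
}

# deletion_record -> feature_vector
.record_features <- function(rec) {
  stopifnot(inherits(rec, "deletion_record"))
  sine_pair <- NULL
  if (!is.null(rec$sine_pair)) {
    sine_pair <- list(identity_percent = rec$sine_pair$identity_percent,
                      alignment_len_bp = rec$sine_pair$alignment_len_bp,
                      orientation = "direct")
  }
  feature_vector(
    mh_len = if (is.na(rec$microhomology_len)) 0L else rec$microhomology_len,
    insertion_len = if (is.na(rec$insertion_seq)) 0L
                    else nchar(rec$insertion_seq),
    insertion_templated = rec$insertion_templated,
    snc_present = rec$snc_present,
    sva_detected = !is.na(rec$sva_family),
    sine_pair = sine_pair
  )
}

#' Classify a table of deletion records
#'
#' Builds a feature vector from each record's feature columns and fills
#' `mechanism_label`.
#'
#' @param records List of [deletion_record()]s.
#' @param thresholds Threshold list.
#' @return The records with `mechanism_label` set.
#' @export
classify_table <- function(records, thresholds = classifier_thresholds()) {
  lapply(records, function(rec) {
    fv <- tryCatch(.record_features(rec), error = function(e) {
      stop("record ", rec$patient_id, ": ", conditionMessage(e),
           call. = FALSE)
    })
    rec$mechanism_label <- classify_mechanism(fv, thresholds)
    rec
  })
}
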