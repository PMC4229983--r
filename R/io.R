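#' Read a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that canonicalizes
#' sequences (uppercase, U mapped to T, other IUPAC codes to N with a
#' warning) and returns plain [sequence_record()] objects in file order.
#'
#' @param path Path to a FASTA file.
#' @return List of `sequence_record`s.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(list())
  # parse as raw strings so RNA-style U and IUPAC codes survive to our
  # canonicalization (DNAStringSet would reject or mangle them)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record '", ids[which(!nzchar(seqs))[1L]],
         "' in ", path)
  }
  mapply(sequence_record, ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequence records as FASTA
#'
#' @param records List of [sequence_record()]s (or a named character vector).
#' @param path Output path.
#' @param width Sequence line width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (is.character(records)) {
    records <- mapply(sequence_record, names(records), records,
                      SIMPLIFY = FALSE, USE.NAMES = FALSE)
  }
  if (length(records) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  seqs <- vapply(records, function(r) r$seq, character(1L))
  ids <- vapply(records, function(r) r$id, character(1L))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta",
                              width = as.integer(width))
  invisible(path)
}

#' Read a BED file into 1-based inclusive intervals
#'
#' BED is 0-based half-open on disk; intervals are converted to the
#' package's 1-based inclusive convention on read.
#'
#' @param path Path to a 3-6 column BED file.
#' @return Data frame with columns contig, start, end (1-based inclusive),
#'   label, score, strand.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "")
  if (ncol(raw) < 3L) stop("BED needs at least 3 columns: ", path)
  out <- data.frame(
    contig = as.character(raw[[1L]]),
    start = as.numeric(raw[[2L]]) + 1,
    end = as.numeric(raw[[3L]]),
    label = if (ncol(raw) >= 4L) as.character(raw[[4L]]) else NA_character_,
    score = if (ncol(raw) >= 5L) raw[[5L]] else NA,
    strand = if (ncol(raw) >= 6L) as.character(raw[[6L]]) else "*",
    stringsAsFactors = FALSE
  )
  if (any(out$end < out$start)) stop("malformed BED interval in ", path)
  out
}

#' Write 1-based inclusive intervals as BED
#'
#' @param intervals Data frame with contig, start, end and optionally
#'   label, score, strand columns (1-based inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("contig", "start", "end") %in% names(intervals)))
  df <- data.frame(
    contig = intervals$contig,
    start = format(intervals$start - 1, scientific = FALSE, trim = TRUE),
    end = format(intervals$end, scientific = FALSE, trim = TRUE),
    label = if ("label" %in% names(intervals)) intervals$label else ".",
    score = if ("score" %in% names(intervals)) intervals$score else 0,
    strand = if ("strand" %in% names(intervals)) intervals$strand else "*",
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# cells printed as "-", en dash, minus sign or empty all mean "absent"
.absent_cell <- function(x) {
  is.na(x) | trimws(x) %in% c("", "-", "–", "−", "—")
}

.parse_flag <- function(x) {
  !(.absent_cell(x)) & toupper(trimws(x)) %in% c("+", "YES", "TRUE", "1")
}

# printed mechanism label -> enum (primary label of compound cells)
.mechanism_from_label <- function(label) {
  l <- tolower(gsub("\\s+", " ", trimws(label)))
  if (grepl("^sva", l)) return("SVA_INSERTION")
  if (grepl("alu", l)) return("ALU_NAHR_MMEJ_RBM")
  if (grepl("^mmej", l)) return("MMEJ_RBM")
  if (grepl("^nhej\\s*/\\s*rbm", l)) return("NHEJ_RBM")
  if (grepl("^nhej", l)) return("NHEJ")
  stop("unrecognized mechanism label: '", label, "'")
}

#' Load a deletion feature table
#'
#' Reads a tab-delimited per-deletion feature table (the dialect of the
#' packaged 17-deletion fixture, see [nf1_deletion_fixture()]). Cells
#' containing "-", an en dash, a minus sign or nothing parse as absent.
#'
#' @param path Path to a TSV with header columns `patient_id`,
#'   `proximal_bp`, `distal_bp`, `size`, `microhomology_bp`,
#'   `insertion_seq`, `insertion_templated`, `sva_family`, `snc`, `mosaic`,
#'   `proximal_location`, `distal_location`, `sine_proximal`,
#'   `sine_distal`, `sine_identity_percent`, `sine_alignment_bp`,
#'   `mechanism`.
#' @return List of [deletion_record()]s.
#' @export
load_deletion_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", encoding = "UTF-8",
                          colClasses = "character")
  if (nrow(df) == 0L) return(list())
  need <- c("patient_id", "proximal_bp", "distal_bp")
  if (!all(need %in% names(df))) {
    stop("deletion table must have columns: ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    num <- function(col) {
      if (!col %in% names(row) || .absent_cell(row[[col]])) return(NA_real_)
      v <- suppressWarnings(as.numeric(gsub(",", "", row[[col]])))
      if (is.na(v)) {
        stop("non-numeric value '", row[[col]], "' in column ", col,
             " for record ", row$patient_id)
      }
      v
    }
    txt <- function(col) {
      if (!col %in% names(row) || .absent_cell(row[[col]])) NA_character_
      else trimws(row[[col]])
    }
    sine_id <- num("sine_identity_percent")
    sine_pair <- NULL
    if (!is.na(sine_id)) {
      sine_pair <- list(name_proximal = txt("sine_proximal"),
                        name_distal = txt("sine_distal"),
                        identity_percent = sine_id,
                        alignment_len_bp = num("sine_alignment_bp"))
    }
    mech <- txt("mechanism")
    rec <- deletion_record(
      patient_id = trimws(row$patient_id),
      proximal_bp = num("proximal_bp"),
      distal_bp = num("distal_bp"),
      microhomology_len = num("microhomology_bp"),
      insertion_seq = txt("insertion_seq"),
      insertion_templated = .parse_flag(row[["insertion_templated"]]),
      sva_family = txt("sva_family"),
      snc_present = .parse_flag(row[["snc"]]),
      mosaic = .parse_flag(row[["mosaic"]]),
      proximal_locus_label = txt("proximal_location"),
      distal_locus_label = txt("distal_location"),
      sine_pair = sine_pair,
      mechanism_label = if (is.na(mech)) NA_character_
                        else .mechanism_from_label(mech)
    )
    rec$mechanism_printed <- mech
    size_col <- num("size")
    rec$size_printed <- size_col
    if (!is.na(size_col) && size_col != rec$size) {
      warning("record ", rec$patient_id, ": printed size ", size_col,
              " != derived size ", rec$size)
    }
    rec
  })
}

#' The packaged 17-deletion breakpoint feature fixture
#'
#' Loads the per-patient breakpoint feature table shipped with the package
#' (17 atypical deletions of the NF1 region at 17q11.2, coordinates on
#' GRCh37/hg19): breakpoint positions, microhomology, microinsertions,
#' single nucleotide changes, mosaicism, flanking SINE annotations and
#' postulated mutational mechanism. One patient appears as "Ak-47055" in
#' the table even though the accompanying text also uses the spelling
#' "Ak-45077"; the fixture keeps the tabular spelling.
#'
#' @return List of 17 [deletion_record()]s.
#' @export
nf1_deletion_fixture <- function() {
  load_deletion_table(system.file("extdata", "nf1_deletions.tsv",
                                  package = "svabreak", mustWork = TRUE))
}

#' Synthetic proxy annotation of the NF1 deletion region
#'
#' A gene/repeat interval annotation of chromosome 17q11.2 built to be
#' consistent with the locus labels of the packaged deletion fixture
#' (SUZ12P spanning 39 kb, flanking genes and low-copy repeats in their
#' reported order). The interval boundaries are synthetic proxies, not
#' genome-browser coordinates; they serve breakpoint-labeling and counting
#' operations.
#'
#' @return Data frame with contig, start, end (1-based inclusive), label.
#' @export
nf1_region_annotation <- function() {
  read_bed(system.file("extdata", "nf1_region_annotation_synthetic.bed",
                       package = "svabreak", mustWork = TRUE))
}
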