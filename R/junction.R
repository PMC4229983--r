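# Junction dissection: anchor an assembled deletion junction onto its
# proximal and distal reference flanks and derive microhomology,
# microinsertion, templated-source hits and flanking single nucleotide
# changes.
#
# Conventions used throughout:
#   * prox_flank is the retained proximal reference sequence whose first
#     base coincides with the first junction base; dist_flank is the
#     retained distal reference sequence whose last base coincides with the
#     last junction base.
#   * Breakpoints within a microhomology tract are reported leftmost:
#     the tract is assigned to the distal side, so the retained proximal
#     segment is the shortest reconstruction-equivalent one.

# Extend an exact anchor, optionally stepping over isolated substitutions
# (candidate SNCs). A mismatch is accepted only if followed by at least
# `match_run` further matching bases, up to `max_snc` mismatches total.
.extend_anchor <- function(jc, fc, from = c("start", "end"),
                           max_snc = 0L, match_run = 8L) {
  from <- match.arg(from)
  if (from == "end") { jc <- rev(jc); fc <- rev(fc) }
  m <- min(length(jc), length(fc))
  a <- 0L
  mismatches <- integer(0)
  while (a < m) {
    if (jc[a + 1L] == fc[a + 1L]) {
      a <- a + 1L
    } else {
      if (length(mismatches) >= max_snc) break
      run_end <- min(m, a + 1L + match_run)
      if (run_end <= a + 1L) break
      idx <- (a + 2L):run_end
      if (run_end - a - 1L >= match_run && all(jc[idx] == fc[idx])) {
        mismatches <- c(mismatches, a + 1L)
        a <- a + 1L
      } else break
    }
  }
  list(len = a, mismatches = mismatches)
}

#' Anchor a junction sequence onto its reference flanks
#'
#' Finds the maximal exact prefix anchor of the junction on the proximal
#' flank and the maximal exact suffix anchor on the distal flank.
#' Optionally tolerates isolated substitutions (candidate single nucleotide
#' changes) inside the anchors. These anchors feed microhomology,
#' insertion and SNC calling.
#'
#' @param junction,prox_flank,dist_flank Nucleotide strings (see module
#'   conventions above).
#' @param min_anchor Minimum anchor length on either side (default 20 bp);
#'   shorter anchors raise a no-call error.
#' @param max_snc Maximum tolerated substitutions per anchor (default 5).
#' @param match_run Matching bases required after a tolerated substitution
#'   (default 8).
#' @return List with `a` (junction bases attributed to the proximal flank),
#'   `b` (attributed to the distal flank), `snc_prox`, `snc_dist`
#'   (mismatch positions, junction coordinates) and `n` (junction length).
#' @export
locate_transition <- function(junction, prox_flank, dist_flank,
                              min_anchor = 20L, max_snc = 5L,
                              match_run = 8L) {
  jc <- seq_chars(junction)
  n <- length(jc)
  if (n < 2L * min_anchor) {
    stop("junction shorter than twice min_anchor (", min_anchor, " bp)")
  }
  pa <- .extend_anchor(jc, seq_chars(prox_flank), "start",
                       max_snc = max_snc, match_run = match_run)
  da <- .extend_anchor(jc, seq_chars(dist_flank), "end",
                       max_snc = max_snc, match_run = match_run)
  if (pa$len < min_anchor) {
    stop("no-call: proximal anchor ", pa$len, " bp < min_anchor ", min_anchor)
  }
  if (da$len < min_anchor) {
    stop("no-call: distal anchor ", da$len, " bp < min_anchor ", min_anchor)
  }
  list(a = pa$len, b = da$len,
       snc_prox = pa$mismatches,
       snc_dist = n + 1L - da$mismatches,
       n = n)
}

#' Microhomology at a deletion junction
#'
#' The microhomology is the maximal junction segment at the transition that
#' is explainable both as the end of the retained proximal flank and as the
#' start of the retained distal flank. Matching is exact; a blunt join has
#' length 0.
#'
#' @inheritParams locate_transition
#' @param min_anchor Minimum exact anchor (default 1 so that short
#'   synthetic examples dissect; raise for real junctions).
#' @return List with `mh_seq`, `mh_len` and `transition` (1-based inclusive
#'   interval of ambiguous junction positions; for a blunt join a
#'   zero-length point `c(k+1, k)` after the last proximal base `k`).
#' @export
compute_microhomology <- function(junction, prox_flank, dist_flank,
                                  min_anchor = 1L) {
  tr <- locate_transition(junction, prox_flank, dist_flank,
                          min_anchor = min_anchor, max_snc = 0L)
  n <- tr$n
  mh_len <- max(0L, tr$a + tr$b - n)
  if (tr$a + tr$b < n) {
    # unexplained middle: insertion junction; microhomology is 0 by the
    # mutually-exclusive convention (see detect_insertion / flank_mh)
    mh_len <- 0L
  }
  if (mh_len > 0L) {
    transition <- c(n - tr$b + 1L, tr$a)
    mh_seq <- substr(junction, transition[1L], transition[2L])
  } else {
    transition <- c(tr$a + 1L, tr$a)
    mh_seq <- ""
  }
  list(mh_seq = mh_seq, mh_len = mh_len, transition = transition)
}

#' Microinsertion at a deletion junction
#'
#' Returns the junction bases explained by neither flank: the segment
#' between the maximal exact prefix match to the proximal flank and the
#' maximal exact suffix match to the distal flank. `NULL` when that span
#' is empty (blunt or microhomology junction).
#'
#' @inheritParams compute_microhomology
#' @return Insertion string or `NULL`.
#' @export
detect_insertion <- function(junction, prox_flank, dist_flank,
                             min_anchor = 1L) {
  tr <- locate_transition(junction, prox_flank, dist_flank,
                          min_anchor = min_anchor, max_snc = 0L)
  if (tr$a + tr$b >= tr$n) return(NULL)
  substr(junction, tr$a + 1L, tr$n - tr$b)
}

# maximal flank-overlap word: suffix of prox flank == prefix of dist flank.
# Reported as `flank_mh` metadata next to an insertion call.
.flank_overlap_mh <- function(prox_flank, dist_flank) {
  m_max <- min(nchar(prox_flank), nchar(dist_flank))
  np <- nchar(prox_flank)
  for (m in m_max:1) {
    if (substr(prox_flank, np - m + 1L, np) == substr(dist_flank, 1L, m)) {
      return(m)
    }
  }
  0L
}

#' Search for the templated source of a microinsertion
#'
#' Scans the sequence context around both breakpoints for matches of the
#' insertion (or its reverse complement) with at most `max_mismatch`
#' mismatches, the signature of a replication-based template switch.
#'
#' @param insertion_seq Insertion string (1-100 bp).
#' @param prox_context Reference sequence upstream of the proximal
#'   breakpoint; its last base abuts the breakpoint.
#' @param dist_context Reference sequence downstream of the distal
#'   breakpoint; its first base abuts the breakpoint.
#' @param window Search window in bp around each breakpoint (default 300).
#' @param max_mismatch Mismatch tolerance; default 1 for insertions up to
#'   11 bp, else 10% of the insertion length.
#' @return Data frame of template hits (source_side, offset, strand,
#'   identity, length) sorted by (mismatches, |offset|). `offset` is the
#'   signed distance of the template start from the breakpoint (negative =
#'   proximal/upstream of the proximal breakpoint; positive = downstream of
#'   the distal breakpoint).
#' @export
find_insertion_template <- function(insertion_seq, prox_context,
                                    dist_context, window = 300L,
                                    max_mismatch = NULL) {
  len <- nchar(insertion_seq)
  stopifnot(len >= 1L, len <= 100L)
  if (is.null(max_mismatch)) {
    max_mismatch <- if (len <= 11L) 1L else max(1L, floor(len * 0.10))
  }
  scan_side <- function(context, side) {
    nc <- nchar(context)
    use <- min(nc, window + len - 1L)
    seg <- if (side == "proximal") {
      substr(context, nc - use + 1L, nc)
    } else {
      substr(context, 1L, use)
    }
    ns <- nchar(seg)
    if (ns < len) return(NULL)
    hits <- list()
    for (strand in c("+", "-")) {
      q <- if (strand == "+") insertion_seq else revcomp(insertion_seq)
      for (s in 1L:(ns - len + 1L)) {
        mm <- hamming(substr(seg, s, s + len - 1L), q)
        if (mm <= max_mismatch) {
          # offset of the template start from the breakpoint: negative
          # upstream of the proximal breakpoint, positive downstream of
          # the distal one
          offset <- if (side == "proximal") s - ns - 1L else s
          hits[[length(hits) + 1L]] <- data.frame(
            source_side = side, offset = offset, strand = strand,
            identity = 100 * (len - mm) / len, length = len,
            mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
    if (length(hits)) do.call(rbind, hits) else NULL
  }
  out <- rbind(scan_side(prox_context, "proximal"),
               scan_side(dist_context, "distal"))
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(source_side = character(0), offset = integer(0),
                      strand = character(0), identity = numeric(0),
                      length = integer(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  out[order(out$mismatches, abs(out$offset)), , drop = FALSE]
}

#' Single nucleotide changes in a breakpoint flank
#'
#' Position-wise comparison of an observed (junction-derived) flank against
#' the aligned reference flank, restricted to `flank_len` bases from the
#' breakpoint and excluding offsets listed as known variants.
#'
#' @param observed,reference Equal-length flank strings. For
#'   `side = "proximal"` the breakpoint abuts the END of both strings; for
#'   `side = "distal"` it abuts the START.
#' @param side "proximal" or "distal".
#' @param flank_len Window from the breakpoint (default 150 bp).
#' @param known_variants Integer offsets (same sign convention as the
#'   return value) to exclude, e.g. catalogued polymorphisms.
#' @return Data frame (side, offset, ref, obs); offsets are negative
#'   upstream of a proximal breakpoint (-1 = closest base) and positive
#'   downstream of a distal breakpoint (+1 = closest base).
#' @export
detect_sncs <- function(observed, reference, side = c("proximal", "distal"),
                        flank_len = 150L, known_variants = integer(0)) {
  side <- match.arg(side)
  if (nchar(observed) != nchar(reference)) {
    stop("observed and reference flanks must have equal length")
  }
  oc <- seq_chars(observed); rc <- seq_chars(reference)
  n <- length(oc)
  offs <- if (side == "proximal") seq_len(n) - n - 1L else seq_len(n)
  keep <- which(oc != rc & abs(offs) <= flank_len & !(offs %in% known_variants))
  data.frame(side = rep(side, length(keep)), offset = offs[keep],
             ref = rc[keep], obs = oc[keep], stringsAsFactors = FALSE)
}

#' Dissect one assembled junction sequence
#'
#' Runs the full junction analysis: anchor the junction onto its reference
#' flanks (tolerating isolated substitutions), derive microhomology or
#' microinsertion (mutually exclusive; any flank-overlap word next to an
#' insertion is reported as `flank_mh` metadata), search for templated
#' insertion sources, and call flanking single nucleotide changes.
#'
#' @param junction_id Identifier for the junction.
#' @param junction,prox_flank,dist_flank Nucleotide strings; the flanks are
#'   the retained reference sequences abutting the junction ends.
#' @param config Optional list overriding `min_anchor` (20), `max_snc` (5),
#'   `match_run` (8), `snc_flank_len` (150), `template_window` (300),
#'   `known_variants` (none).
#' @return A `junction_call` list: transition interval, `mh_seq`/`mh_len`,
#'   `insertion_seq`, `flank_mh`, `template_hits`, `sncs`,
#'   `breakpoint_proximal` (index in `prox_flank` of the last retained base,
#'   leftmost convention) and `breakpoint_distal` (index in `dist_flank` of
#'   the first retained base).
#' @export
characterize_junction <- function(junction_id, junction, prox_flank,
                                  dist_flank, config = list()) {
  cfg <- utils::modifyList(list(min_anchor = 20L, max_snc = 5L,
                                match_run = 8L, snc_flank_len = 150L,
                                template_window = 300L,
                                known_variants = integer(0)), config)
  tr <- locate_transition(junction, prox_flank, dist_flank,
                          min_anchor = cfg$min_anchor,
                          max_snc = cfg$max_snc, match_run = cfg$match_run)
  n <- tr$n; a <- tr$a; b <- tr$b
  insertion <- NULL; flank_mh <- 0L
  if (a + b >= n) {
    mh_len <- a + b - n
    if (mh_len > 0L) {
      transition <- c(n - b + 1L, a)
      mh_seq <- substr(junction, transition[1L], transition[2L])
    } else {
      transition <- c(a + 1L, a)
      mh_seq <- ""
    }
  } else {
    insertion <- substr(junction, a + 1L, n - b)
    mh_len <- 0L; mh_seq <- ""
    transition <- c(a + 1L, n - b)
    flank_mh <- .flank_overlap_mh(prox_flank, dist_flank)
  }
  # leftmost convention: the mh tract belongs to the distal side
  bp_prox <- a - mh_len
  bp_dist <- nchar(dist_flank) - b + 1L
  template_hits <- if (!is.null(insertion) && nchar(insertion) <= 100L) {
    # microinsertions only; larger inserted segments (e.g. retroelement
    # copies) go to the SVA annotation route instead
    find_insertion_template(insertion, prox_flank, dist_flank,
                            window = cfg$template_window)
  } else {
    data.frame(source_side = character(0), offset = integer(0),
               strand = character(0), identity = numeric(0),
               length = integer(0), mismatches = integer(0),
               stringsAsFactors = FALSE)
  }
  # SNCs from the anchored prefix/suffix, position-aligned to the flanks
  prox_obs <- substr(junction, 1L, a)
  prox_ref <- substr(prox_flank, 1L, a)
  dist_obs <- substr(junction, n - b + 1L, n)
  dist_ref <- substr(dist_flank, nchar(dist_flank) - b + 1L,
                     nchar(dist_flank))
  sncs <- rbind(
    detect_sncs(prox_obs, prox_ref, "proximal",
                flank_len = cfg$snc_flank_len,
                known_variants = cfg$known_variants),
    detect_sncs(dist_obs, dist_ref, "distal",
                flank_len = cfg$snc_flank_len,
                known_variants = cfg$known_variants)
  )
  structure(list(
    junction_id = junction_id,
    transition = transition,
    mh_seq = mh_seq, mh_len = mh_len,
    insertion_seq = insertion, flank_mh = flank_mh,
    template_hits = template_hits,
    sncs = sncs,
    breakpoint_proximal = bp_prox,
    breakpoint_distal = bp_dist
  ), class = "junction_call")
}

#' @export
print.junction_call <- function(x, ...) {
  cat(sprintf("<junction_call> %s: mh=%d%s, %d template hit(s), %d SNC(s)\n",
              x$junction_id, x$mh_len,
              if (!is.null(x$insertion_seq))
                sprintf(", insertion=%s", x$insertion_seq) else "",
              nrow(x$template_hits), nrow(x$sncs)))
  invisible(x)
}
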