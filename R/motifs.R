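# Repeat and motif scanners for breakpoint-flanking sequence analysis.
# These are in-package equivalents of the external tools commonly used for
# such scans (non-B DNA repeat searches, BLASTN self-alignment,
# RepeatMasker-style track lookups): direct/inverted repeats at bounded arm
# and spacer sizes, larger self-alignment repeats by seed-and-extend, L1
# endonuclease cleavage motifs, homopolymer tracts, GC content and global
# pairwise identity.

# mask homopolymer runs >= min_run with N so polyA/polyT tracts do not
# flood the direct/inverted repeat hit lists
.mask_homopolymers <- function(x, min_run = 8L) {
  r <- rle(x)
  long <- r$values %in% c("A", "C", "G", "T") & r$lengths >= min_run
  if (any(long)) {
    r$values[long] <- "N"
    x <- inverse.rle(r)
  }
  x
}

.empty_repeat_hits <- function() {
  data.frame(kind = character(0), start1 = integer(0), start2 = integer(0),
             arm_len = integer(0), spacer = integer(0), identity = numeric(0),
             strand_relation = character(0), stringsAsFactors = FALSE)
}

#' Direct repeats within bounded arm and spacer sizes
#'
#' Finds exact same-strand repeat pairs with arm length in
#' `[min_arm, max_arm]` separated by at most `max_spacer` bp. Matches are
#' maximal runs at each copy offset; runs longer than `max_arm` are
#' reported clipped at `max_arm`. Homopolymer runs of 8 bp or more are
#' masked before the search.
#'
#' @param seq Nucleotide string.
#' @param min_arm,max_arm Arm length bounds in bp (defaults 10 and 150).
#' @param max_spacer Maximum bp between the two arms (default 9,
#'   i.e. "separated by < 10 bp").
#' @param mask_run Homopolymer length triggering masking (default 8).
#' @return Data frame of hits: kind, start1, start2 (1-based arm starts),
#'   arm_len, spacer, identity (always 100), strand_relation ("same").
#' @export
find_direct_repeats <- function(seq, min_arm = 10L, max_arm = 150L,
                                max_spacer = 9L, mask_run = 8L) {
  x <- .mask_homopolymers(seq_chars(seq), mask_run)
  n <- length(x)
  if (n < 2L * min_arm) return(.empty_repeat_hits())
  hits <- list()
  for (d in min_arm:min(n - 1L, max_arm + max_spacer)) {
    i1 <- seq_len(n - d)
    eq <- x[i1] == x[i1 + d] & x[i1] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_arm)) {
      len <- r$lengths[k]
      arm <- min(len, max_arm, d)
      spacer <- d - arm
      if (arm >= min_arm && spacer >= 0L && spacer <= max_spacer) {
        hits[[length(hits) + 1L]] <- data.frame(
          kind = "direct", start1 = starts[k], start2 = starts[k] + d,
          arm_len = arm, spacer = spacer, identity = 100,
          strand_relation = "same", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else .empty_repeat_hits()
}

#' Inverted repeats within bounded arm and spacer sizes
#'
#' Finds exact inverted (reverse-complement) repeat pairs with arm length
#' in `[min_arm, max_arm]` and spacer at most `max_spacer` bp. Matches are
#' maximal runs along each anti-diagonal; runs longer than `max_arm` are
#' clipped at the outer ends. Homopolymers are masked as in
#' [find_direct_repeats()].
#'
#' @inheritParams find_direct_repeats
#' @param min_arm,max_arm Arm bounds (defaults 6 and 150).
#' @param max_spacer Maximum loop/spacer (default 99, "separated by
#'   < 100 bp").
#' @return Data frame as in [find_direct_repeats()] with
#'   strand_relation "revcomp"; start2 is the start of the downstream arm.
#' @export
find_inverted_repeats <- function(seq, min_arm = 6L, max_arm = 150L,
                                  max_spacer = 99L, mask_run = 8L) {
  x <- .mask_homopolymers(seq_chars(seq), mask_run)
  cx <- comp_chars(x)
  n <- length(x)
  if (n < 2L * min_arm) return(.empty_repeat_hits())
  hits <- list()
  for (s in (2L * min_arm + 1L):(2L * n - 1L)) {
    p_max <- min((s - 1L) %/% 2L, n - 1L)
    p_min <- max(1L, s - n)
    if (p_max - p_min + 1L < min_arm) next
    p <- p_min:p_max
    eq <- x[p] == cx[s - p] & x[p] != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_arm)) {
      p2 <- p[ends[k]]                      # innermost matched position
      spacer <- s - 2L * p2 - 1L
      if (spacer > max_spacer) next
      arm <- min(r$lengths[k], max_arm)
      p1 <- p2 - arm + 1L
      hits[[length(hits) + 1L]] <- data.frame(
        kind = "inverted", start1 = p1, start2 = s - p2,
        arm_len = arm, spacer = spacer, identity = 100,
        strand_relation = "revcomp", stringsAsFactors = FALSE)
    }
  }
  if (length(hits)) do.call(rbind, hits) else .empty_repeat_hits()
}

# ungapped X-drop extension along a (anti-)diagonal; returns the maximal
# scoring segment through the seed. `pairs_eq` is the logical match vector
# indexed along the diagonal, `seed` an index range known to match.
.xdrop_extend <- function(pairs_eq, seed_lo, seed_hi, xdrop = 15,
                          match = 1, mismatch = -2) {
  n <- length(pairs_eq)
  sc <- function(i) if (pairs_eq[i]) match else mismatch
  best <- 0; cur <- 0; hi <- seed_hi
  i <- seed_hi
  while (i < n) {
    i <- i + 1L
    cur <- cur + sc(i)
    if (cur > best) { best <- cur; hi <- i }
    if (cur < best - xdrop) break
  }
  best <- 0; cur <- 0; lo <- seed_lo
  i <- seed_lo
  while (i > 1L) {
    i <- i - 1L
    cur <- cur + sc(i)
    if (cur > best) { best <- cur; lo <- i }
    if (cur < best - xdrop) break
  }
  c(lo, hi)
}

# collapse hits to maximal arms: drop any hit whose both arms are
# contained in another hit's arms (same kind)
.collapse_contained <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  e1 <- hits$start1 + hits$arm_len - 1L
  e2 <- hits$start2 + hits$arm_len - 1L
  keep <- rep(TRUE, nrow(hits))
  ord <- order(-hits$arm_len)
  for (ii in seq_along(ord)) {
    i <- ord[ii]
    if (!keep[i]) next
    inside <- hits$start1 >= hits$start1[i] & e1 <= e1[i] &
      hits$start2 >= hits$start2[i] & e2 <= e2[i] &
      hits$kind == hits$kind[i]
    inside[i] <- FALSE
    keep[inside] <- FALSE
  }
  hits[keep, , drop = FALSE]
}

#' Large repeats by self-alignment (seed and extend)
#'
#' Aligns a sequence window against itself (direct) and against its
#' reverse complement (inverted) using exact 11-mer seeds, ungapped X-drop
#' extension and collapsing to maximal arms, reporting off-diagonal
#' repeats with arm at least `min_len` and identity at least
#' `min_identity` percent. Intended for windows up to a few tens of kb.
#'
#' @param seq Nucleotide string (window, at most 50 kb).
#' @param min_len Minimum arm length in bp (default 151, i.e. repeats
#'   larger than the short-repeat scanners handle).
#' @param min_identity Minimum percent identity (default 87).
#' @param seed_len Exact seed length (default 11).
#' @param xdrop X-drop threshold for the ungapped extension (default 15).
#' @return Data frame of hits with kind "self_align", strand_relation
#'   "same" or "revcomp", realized identity and arm coordinates
#'   (start2 > start1 for direct hits; for revcomp hits start2 is the
#'   start of the second arm on the forward strand).
#' @export
self_align_repeats <- function(seq, min_len = 151L, min_identity = 87,
                               seed_len = 11L, xdrop = 15) {
  n <- nchar(seq)
  if (n > 50000L) stop("self-alignment window limited to 50 kb")
  if (n < 2L * min_len) return(.empty_repeat_hits())
  x <- .mask_homopolymers(seq_chars(seq), 8L)
  cx <- comp_chars(x)
  kmers_at <- function(chars) {
    m <- length(chars) - seed_len + 1L
    if (m < 1L) return(character(0))
    out <- substring(chars_seq(chars), seq_len(m), seq_len(m) + seed_len - 1L)
    out[grepl("N", out, fixed = TRUE)] <- NA
    out
  }
  km <- kmers_at(x)
  idx <- split(seq_along(km)[!is.na(km)], km[!is.na(km)])
  idx <- idx[lengths(idx) >= 2L]
  hits <- list()

  # --- direct: diagonals d = p2 - p1 > 0
  diag_seeds <- new.env(parent = emptyenv())
  for (pos in idx) {
    if (length(pos) > 25L) next   # highly repetitive seed, skip
    cmb <- utils::combn(pos, 2L)
    for (j in seq_len(ncol(cmb))) {
      d <- cmb[2L, j] - cmb[1L, j]
      key <- as.character(d)
      diag_seeds[[key]] <- c(diag_seeds[[key]], cmb[1L, j])
    }
  }
  for (key in ls(diag_seeds)) {
    d <- as.integer(key)
    i1 <- seq_len(n - d)
    eq <- x[i1] == x[i1 + d] & x[i1] != "N"
    seeds <- sort(unique(diag_seeds[[key]]))
    covered <- integer(0)
    for (s0 in seeds) {
      if (s0 %in% covered) next
      span <- .xdrop_extend(eq, s0, min(s0 + seed_len - 1L, length(eq)),
                            xdrop = xdrop)
      covered <- union(covered, span[1L]:span[2L])
      arm <- span[2L] - span[1L] + 1L
      ident <- 100 * sum(eq[span[1L]:span[2L]]) / arm
      if (arm >= min_len && ident >= min_identity && arm <= d) {
        hits[[length(hits) + 1L]] <- data.frame(
          kind = "self_align", start1 = span[1L], start2 = span[1L] + d,
          arm_len = arm, spacer = d - arm, identity = ident,
          strand_relation = "same", stringsAsFactors = FALSE)
      }
    }
  }

  # --- inverted: seeds of x matching seeds of revcomp arm; anti-diagonal
  # s = p1 + p2 + seed_len - 1 pairs position p with s - p
  rc_km <- vapply(seq_along(km), function(i) {
    if (is.na(km[i])) NA_character_ else {
      paste(rev(comp_chars(strsplit(km[i], "")[[1L]])), collapse = "")
    }
  }, character(1L))
  anti_seeds <- new.env(parent = emptyenv())
  pos_by_kmer <- split(seq_along(km)[!is.na(km)], km[!is.na(km)])
  for (i in seq_along(rc_km)) {
    k <- rc_km[i]
    if (is.na(k)) next
    partners <- pos_by_kmer[[k]]
    if (is.null(partners)) next
    for (p2 in partners[partners > i + seed_len - 1L]) {
      s <- i + p2 + seed_len - 1L
      key <- as.character(s)
      anti_seeds[[key]] <- c(anti_seeds[[key]], i)
    }
  }
  for (key in ls(anti_seeds)) {
    s <- as.integer(key)
    p_max <- min((s - 1L) %/% 2L, n)
    p_min <- max(1L, s - n)
    if (p_max < p_min) next
    p <- p_min:p_max
    eq <- x[p] == cx[s - p] & x[p] != "N"
    seeds <- sort(unique(anti_seeds[[key]]))
    covered <- integer(0)
    for (s0 in seeds) {
      s0i <- s0 - p_min + 1L
      if (s0i < 1L || s0i > length(eq) || s0i %in% covered) next
      hi <- min(s0i + seed_len - 1L, length(eq))
      span <- .xdrop_extend(eq, s0i, hi, xdrop = xdrop)
      covered <- union(covered, span[1L]:span[2L])
      arm <- span[2L] - span[1L] + 1L
      ident <- 100 * sum(eq[span[1L]:span[2L]]) / arm
      p2_in <- p[span[2L]]
      spacer <- s - 2L * p2_in - 1L
      if (arm >= min_len && ident >= min_identity && spacer >= 0L) {
        hits[[length(hits) + 1L]] <- data.frame(
          kind = "self_align", start1 = p[span[1L]], start2 = s - p2_in,
          arm_len = arm, spacer = spacer, identity = ident,
          strand_relation = "revcomp", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(.empty_repeat_hits())
  .collapse_contained(do.call(rbind, hits))
}

#' L1 endonuclease consensus cleavage sites
#'
#' Scans both strands for the consensus cleavage motifs 5'-TTTT/A-3' and
#' 5'-CTTT/A-3'. The cut lies between the 4th and 5th motif base;
#' `cleavage_pos` is the forward-strand position of the base 5' of the cut
#' (for a plus-strand motif starting at `p`, the cut is between `p+3` and
#' `p+4`, so `cleavage_pos = p+3`).
#'
#' @param seq Nucleotide string.
#' @param strands Strands to scan (default both).
#' @return Data frame (motif, start, cleavage_pos, strand); minus-strand
#'   hits are reverse-complement occurrences reported in forward
#'   coordinates with `start` the leftmost motif base.
#' @export
scan_l1_en_sites <- function(seq, strands = c("+", "-")) {
  out <- list()
  find_all <- function(pattern) {
    m <- gregexpr(pattern, seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m)
  }
  if ("+" %in% strands) {
    for (p in find_all("(?=([CT]TTTA))")) {
      motif <- paste0(substr(seq, p, p), "TTT/A")
      out[[length(out) + 1L]] <- data.frame(
        motif = motif, start = p, cleavage_pos = p + 3L, strand = "+",
        stringsAsFactors = FALSE)
    }
  }
  if ("-" %in% strands) {
    # revcomp of [CT]TTTA is TAAA[AG]; minus-strand cut maps between
    # forward positions p and p+1 for a motif starting at p
    for (p in find_all("(?=(TAAA[AG]))")) {
      motif <- if (substr(seq, p + 4L, p + 4L) == "G") "CTTT/A" else "TTTT/A"
      out[[length(out) + 1L]] <- data.frame(
        motif = motif, start = p, cleavage_pos = p, strand = "-",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(motif = character(0), start = integer(0),
                      cleavage_pos = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), , drop = FALSE]
}

#' Maximal homopolymer tracts
#'
#' @param seq Nucleotide string.
#' @param base Single base A/C/G/T.
#' @param min_len Minimum run length.
#' @return Data frame (start, end, length) of maximal runs of `base` with
#'   length at least `min_len`.
#' @export
find_homopolymer_tracts <- function(seq, base, min_len = 10L) {
  stopifnot(base %in% c("A", "C", "G", "T"))
  x <- seq_chars(seq)
  r <- rle(x == base)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- which(r$values & r$lengths >= min_len)
  data.frame(start = starts[k], end = ends[k], length = r$lengths[k])
}

#' GC content
#'
#' Fraction (G+C)/(A+C+G+T); N is excluded from the denominator. With a
#' window size, returns one fraction per non-overlapping window (trailing
#' partial window included); an all-N window yields `NaN`.
#'
#' @param seq Nucleotide string.
#' @param window Window size in bp, or `NULL` for the whole sequence.
#' @return Numeric fraction, or vector of per-window fractions.
#' @export
gc_content <- function(seq, window = NULL) {
  one <- function(s) {
    x <- seq_chars(s)
    acgt <- sum(x %in% c("A", "C", "G", "T"))
    if (acgt == 0L) return(NaN)
    sum(x %in% c("G", "C")) / acgt
  }
  if (is.null(window)) return(one(seq))
  n <- nchar(seq)
  starts <- seq(1L, n, by = window)
  vapply(starts, function(s) one(substr(seq, s, min(n, s + window - 1L))),
         numeric(1L))
}

#' Global pairwise identity
#'
#' Needleman-Wunsch global alignment with affine gaps (match 1,
#' mismatch -1, gap open -2, gap extend -0.5 by default) via
#' [Biostrings::pairwiseAlignment()]. Identity is matches over alignment
#' columns. With `orientation = "both"` the reverse complement of `b` is
#' also tried and the better-scoring normalization reported.
#'
#' @param a,b Nucleotide strings.
#' @param orientation "forward" (default) or "both".
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return List: identity (percent), alignment_len (columns), score,
#'   strand ("+" or "-", the orientation of `b` used).
#' @export
pairwise_identity <- function(a, b, orientation = c("forward", "both"),
                              match = 1, mismatch = -1, gap_open = 2,
                              gap_extend = 0.5) {
  orientation <- match.arg(orientation)
  stopifnot(nzchar(a), nzchar(b))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  align <- function(bb) {
    Biostrings::pairwiseAlignment(a, bb, type = "global",
                                  substitutionMatrix = mat,
                                  gapOpening = gap_open,
                                  gapExtension = gap_extend)
  }
  aln <- align(b); strand <- "+"
  if (orientation == "both") {
    aln_rc <- align(revcomp(b))
    if (Biostrings::score(aln_rc) > Biostrings::score(aln)) {
      aln <- aln_rc; strand <- "-"
    }
  }
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  list(identity = Biostrings::pid(aln, type = "PID1"),
       alignment_len = cols,
       score = Biostrings::score(aln),
       strand = strand)
}
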