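# SVA retrotransposon modeling and annotation. SVA elements are composite
# hominid retrotransposons: (CCCTCT)n hexamer, Alu-like region, extremely
# GC-rich VNTR, SINE-R, polyA tail, optionally flanked by target site
# duplications and carrying 5'/3' transductions. 5'-truncated copies keep
# the 3' components; SINE-R presence is the minimal requirement for an
# SVA call here because it is the 3'-most diagnostic component and
# survives truncation.

#' Build an SVA source-element model
#'
#' Constructs a synthetic source element with the canonical component
#' order 5'->3': optional 5' transduction, (CCCTCT)n hexamer, Alu-like
#' region, GC-rich VNTR (tandem copies of a unit with light divergence),
#' SINE-R, polyA tract. Component spans are recorded for downstream
#' boundary mapping.
#'
#' @param source_id Identifier (e.g. a locus-style name).
#' @param hexamer_n Hexamer unit count (default 4).
#' @param alu_like_len Alu-like region length (default 343 bp).
#' @param vntr_len VNTR length in bp.
#' @param vntr_gc VNTR GC fraction (default 0.79; must be >= 0.7).
#' @param sine_r_len SINE-R length (default 490 bp).
#' @param polya_len PolyA tail length.
#' @param five_td_len 5' transduction length (0 for none).
#' @param subfamily Subfamily label carried through annotation (never
#'   inferred).
#' @return List with class `sva_source`: `source_id`, `seq`, `components`
#'   (data frame name/start/end), `total_len`, `subfamily`.
#' @export
sva_source <- function(source_id, hexamer_n = 4L, alu_like_len = 343L,
                       vntr_len = 1823L, vntr_gc = 0.79,
                       sine_r_len = 490L, polya_len = 11L,
                       five_td_len = 0L, subfamily = NA_character_) {
  stopifnot(vntr_gc >= 0.7, hexamer_n >= 1L, vntr_len >= 300L,
            sine_r_len >= 100L, polya_len >= 5L)
  unit <- random_dna(37L, vntr_gc)
  reps <- ceiling(vntr_len / 37L)
  vntr <- substr(strrep(unit, reps), 1L, vntr_len)
  vc <- seq_chars(vntr)
  jitter <- sample(vntr_len, max(1L, round(vntr_len * 0.03)))
  for (i in jitter) vc[i] <- sample(c("G", "C", "A", "T"), 1L,
                                    prob = c(.4, .4, .1, .1))
  parts <- list()
  if (five_td_len > 0L) parts$five_TD <- random_dna(five_td_len, 0.45)
  parts$hexamer <- strrep("CCCTCT", hexamer_n)
  parts$Alu_like <- random_dna(alu_like_len, 0.55)
  parts$VNTR <- chars_seq(vc)
  parts$SINE_R <- random_dna(sine_r_len, 0.52)
  parts$polyA <- strrep("A", polya_len)
  lens <- vapply(parts, nchar, integer(1L))
  ends <- cumsum(lens)
  comps <- data.frame(name = names(parts),
                      start = ends - lens + 1L, end = ends,
                      stringsAsFactors = FALSE)
  structure(list(source_id = source_id,
                 seq = paste(unlist(parts), collapse = ""),
                 components = comps,
                 total_len = sum(lens),
                 hexamer_n = hexamer_n,
                 subfamily = subfamily),
            class = "sva_source")
}

#' Default two-element SVA source library
#'
#' Two synthetic source models emulating the size classes of highly
#' active human source elements: a 4,039 bp element with a 2,093 bp VNTR
#' at 79% GC carrying a 5' transduction (subfamily label SVA_F1-like) and
#' a 2,691 bp element without transduction (SVA_F-like). Sequences are
#' random within each component model, so the two sources are unrelated
#' outside their shared hexamer/polyA motifs.
#'
#' @param seed RNG seed for the library.
#' @return Named list of two [sva_source()] objects.
#' @export
sva_source_library <- function(seed = 1L) {
  set.seed(seed)
  s1 <- sva_source("SVA_F1_synth_H10like", hexamer_n = 4L,
                   alu_like_len = 343L, vntr_len = 2093L, vntr_gc = 0.79,
                   sine_r_len = 490L, polya_len = 17L, five_td_len = 1072L,
                   subfamily = "SVA_F1")
  s2 <- sva_source("SVA_F_synth_H6like", hexamer_n = 4L,
                   alu_like_len = 343L, vntr_len = 1823L, vntr_gc = 0.79,
                   sine_r_len = 490L, polya_len = 11L, five_td_len = 0L,
                   subfamily = "SVA_F")
  stats::setNames(list(s1, s2), c(s1$source_id, s2$source_id))
}

# quick exact-seed prefilter: does any 25-mer probe from the source occur
# in the query (forward or reverse-complement)?
.sva_seed_hit <- function(query, source_seq, probe_len = 25L, every = 150L) {
  starts <- seq(1L, nchar(source_seq) - probe_len + 1L, by = every)
  rcq <- revcomp(query)
  for (s in starts) {
    probe <- substr(source_seq, s, s + probe_len - 1L)
    if (grepl(probe, query, fixed = TRUE) ||
        grepl(probe, rcq, fixed = TRUE)) {
      return(TRUE)
    }
  }
  FALSE
}

#' Annotate an SVA element in a query sequence
#'
#' Locates the best-matching source element by local alignment of each
#' library source against the query (both orientations), maps the source's
#' component boundaries onto the query, measures polyA and VNTR GC on the
#' query, and derives the 5' truncation offset. Returns `NULL` when no
#' source aligns at `min_identity` or the aligned span does not retain the
#' SINE-R (the minimal requirement for an SVA call).
#'
#' @param query Nucleotide string (an inserted copy, or a whole junction
#'   containing one); at least 300 bp.
#' @param sources List of [sva_source()] objects (non-empty).
#' @param min_identity Minimum percent identity over the aligned span
#'   (default 90).
#' @return List with class `sva_annotation`: `element_span` (on the
#'   query), `components` (name/start/end/query coordinates, plus
#'   `vntr_gc` and `polya_len` attributes), `truncation_offset`,
#'   `source_id`, `source_identity`, `orientation`; or `NULL`.
#' @export
annotate_sva <- function(query, sources, min_identity = 90) {
  if (length(sources) == 0L) stop("empty SVA source library")
  if (nchar(query) < 300L) return(NULL)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  best <- NULL
  for (src in sources) {
    if (!.sva_seed_hit(query, src$seq)) next
    for (ori in c("+", "-")) {
      q <- if (ori == "+") query else revcomp(query)
      aln <- Biostrings::pairwiseAlignment(
        src$seq, q, type = "local", substitutionMatrix = mat,
        gapOpening = 5, gapExtension = 2)
      ident <- Biostrings::pid(aln, type = "PID1")
      sp <- Biostrings::subject(aln)
      pt <- Biostrings::pattern(aln)
      span_len <- Biostrings::nchar(sp)
      if (span_len < 300L || ident < min_identity) next
      cand <- list(src = src, ident = ident,
                   q_start = Biostrings::start(sp@range),
                   q_end = Biostrings::end(sp@range),
                   s_start = Biostrings::start(pt@range),
                   s_end = Biostrings::end(pt@range),
                   orientation = ori, score = Biostrings::score(aln))
      if (is.null(best) || cand$score > best$score) best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  src <- best$src
  # map component boundaries (ungapped offset mapping over the aligned span)
  shift <- best$q_start - best$s_start
  comp <- src$components
  comp <- comp[comp$end >= best$s_start & comp$start <= best$s_end, ,
               drop = FALSE]
  if (!"SINE_R" %in% comp$name) return(NULL)
  comp$start <- pmax(comp$start, best$s_start) + shift
  comp$end <- pmin(comp$end, best$s_end) + shift
  qlen_coord <- nchar(query)
  if (best$orientation == "-") {
    # report on the forward strand of the query
    new_start <- qlen_coord - comp$end + 1L
    comp$end <- qlen_coord - comp$start + 1L
    comp$start <- new_start
    comp <- comp[rev(seq_len(nrow(comp))), , drop = FALSE]
    el_span <- c(qlen_coord - best$q_end + 1L, qlen_coord - best$q_start + 1L)
  } else {
    el_span <- c(best$q_start, best$q_end)
  }
  q_oriented <- if (best$orientation == "+") query else revcomp(query)
  vntr_gc <- NA_real_
  vrow <- comp[comp$name == "VNTR", , drop = FALSE]
  if (nrow(vrow) == 1L) {
    vq <- if (best$orientation == "+") {
      substr(query, vrow$start, vrow$end)
    } else {
      substr(q_oriented, qlen_coord - vrow$end + 1L,
             qlen_coord - vrow$start + 1L)
    }
    vntr_gc <- gc_content(vq)
  }
  # measured polyA at the element 3' end (oriented)
  tail_seq <- substr(q_oriented, max(1L, best$q_end - 60L), best$q_end)
  runs <- find_homopolymer_tracts(tail_seq, "A", min_len = 5L)
  polya_len <- if (nrow(runs)) max(runs$length) else 0L
  structure(list(
    element_span = el_span,
    components = comp,
    vntr_gc = vntr_gc,
    polya_len = polya_len,
    truncation_offset = best$s_start - 1L,
    source_id = src$source_id,
    subfamily = src$subfamily,
    source_identity = best$ident,
    orientation = best$orientation
  ), class = "sva_annotation")
}

#' Target site duplication at an insertion
#'
#' The TSD is the longest exact word that both ends the left flank (its
#' last base abutting the insertion) and starts the right flank, with
#' length within `[min_len, max_len]`. Deletion-associated insertions
#' resolved by ligation to a distal break carry no TSD.
#'
#' @param left_flank,right_flank Flanks immediately outside the inserted
#'   element (each at least `max_len` long).
#' @param max_len,min_len Length bounds (defaults 25 and 5).
#' @return List(tsd_seq, left_span, right_span) or `NULL`.
#' @export
detect_tsd <- function(left_flank, right_flank, max_len = 25L,
                       min_len = 5L) {
  stopifnot(nchar(left_flank) >= max_len, nchar(right_flank) >= max_len)
  nl <- nchar(left_flank)
  for (len in max_len:min_len) {
    w <- substr(left_flank, nl - len + 1L, nl)
    if (w == substr(right_flank, 1L, len)) {
      return(list(tsd_seq = w,
                  left_span = c(nl - len + 1L, nl),
                  right_span = c(1L, len)))
    }
  }
  NULL
}

#' Classify an annotated SVA copy as full length or 5'-truncated
#'
#' @param annotation An `sva_annotation`.
#' @param threshold Truncation offsets above this many bp count as
#'   truncated (default 50, i.e. minor 5' raggedness still counts as full
#'   length).
#' @return "full_length" or "five_prime_truncated".
#' @export
classify_truncation <- function(annotation, threshold = 50L) {
  stopifnot(inherits(annotation, "sva_annotation"))
  if (annotation$truncation_offset > threshold) {
    "five_prime_truncated"
  } else {
    "full_length"
  }
}

#' Target-primed reverse transcription hallmarks at an integration site
#'
#' Flags the four TPRT signatures around an annotated SVA insertion:
#' an L1 endonuclease cleavage context at the integration site, a polyT
#' tract at the proximal side of the insertion, a polyA tail at the
#' element 3' end, and a GC-rich VNTR. The endonuclease flag is read from
#' the proximal reference flank, whose retained end at a cleavage-point
#' breakpoint terminates in [C/T]TTT (the A of the [C/T]TTT/A consensus
#' lies on the deleted side).
#'
#' @param junction Junction nucleotide string.
#' @param annotation `sva_annotation` of the junction (element span in
#'   junction coordinates).
#' @param prox_flank Proximal reference flank (its end abuts the
#'   breakpoint). If `NULL`, the junction sequence 5' of the insertion is
#'   used.
#' @param min_polyt Minimum polyT run length (default 10).
#' @return List of logical flags `en_site_at_integration`, `polyt_tract`,
#'   `polya_tail`, `vntr_gc_high` plus supporting coordinates/values.
#' @export
tprt_hallmarks <- function(junction, annotation, prox_flank = NULL,
                           min_polyt = 10L) {
  stopifnot(inherits(annotation, "sva_annotation"))
  el <- annotation$element_span
  upstream <- substr(junction, 1L, el[1L] - 1L)
  # polyT tract ending at (or within 2 bp of) the element start
  runs <- find_homopolymer_tracts(upstream, "T", min_len = min_polyt)
  polyt <- nrow(runs) > 0L && any(runs$end >= nchar(upstream) - 2L)
  polyt_len <- if (nrow(runs)) max(runs$length) else 0L
  # endonuclease cleavage context: retained proximal end in [C/T]TTT
  en_ctx <- if (!is.null(prox_flank)) prox_flank else {
    # strip the polyT tract to expose the flank end
    if (nrow(runs)) substr(upstream, 1L, runs$start[which.max(runs$end)] - 1L)
    else upstream
  }
  en_site <- grepl("[CT]TTT$", en_ctx) ||
    (nzchar(en_ctx) && grepl("[CT]$", en_ctx) && polyt)
  list(en_site_at_integration = en_site,
       polyt_tract = polyt,
       polyt_len = polyt_len,
       polya_tail = annotation$polya_len >= 5L,
       vntr_gc_high = !is.na(annotation$vntr_gc) &&
         annotation$vntr_gc >= 0.7,
       vntr_gc = annotation$vntr_gc)
}
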