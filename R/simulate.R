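# Synthetic deletion-junction generator. Every mutational mechanism the
# classifier knows is simulated with full ground truth, at desk scale:
# one 20 kb reference contig per junction, deletions of 5-12 kb, 300 bp
# retained flanks. Junction signatures (microhomology length, templated
# microinsertion, flanking SNCs, Alu-pair homology, SVA TPRT hallmarks)
# are identical to their full-size genomic counterparts.
#
# Flank convention (mirrors the junction module): the emitted proximal
# flank ends at the RIGHTMOST reconstruction-equivalent breakpoint, the
# distal flank starts at the LEFTMOST one, so both flanks contain the
# microhomology tract once and the junction is
#   prox_flank ++ [insertion] ++ dist_flank[mh+1 ..].

#' Simulation configuration
#'
#' @param contig_len Reference contig length in bp (default 20 kb).
#' @param gc_fraction Target GC of the random background (default 0.41,
#'   genome-like).
#' @param seed Master seed; a fixed seed makes every output byte-identical.
#' @param n_per_mechanism Junctions per mechanism in a cohort (default 10).
#' @param deletion_size_range Deleted-segment size range in bp.
#' @param mh_range_nhej Microhomology range (bp) for NHEJ joins (0-4).
#' @param mh_range_mmej Microhomology range (bp) for MMEJ joins (6-52).
#' @param insertion_len_range Templated microinsertion lengths (9-11 bp).
#' @param snc_rate Probability that an insertion-bearing replication-based
#'   junction additionally carries flanking SNCs.
#' @param sva_truncation_range 5' truncation offsets (bp) for inserted SVA
#'   copies, capped so the VNTR 3' portion, SINE-R and polyA survive.
#' @param polyT_len Length of the polyT tract at TPRT integration sites
#'   (default 40).
#' @param en_motif Endonuclease consensus planted at integration sites.
#' @param flank_len Retained reference flank emitted per side (default 300).
#' @return List with class `sim_config`.
#' @export
sim_config <- function(contig_len = 20000L, gc_fraction = 0.41, seed = 1L,
                       n_per_mechanism = 10L,
                       deletion_size_range = c(5000L, 12000L),
                       mh_range_nhej = c(0L, 4L),
                       mh_range_mmej = c(6L, 52L),
                       insertion_len_range = c(9L, 11L),
                       snc_rate = 0.25,
                       sva_truncation_range = c(0L, 2200L),
                       polyT_len = 40L,
                       en_motif = "CTTTA",
                       flank_len = 300L) {
  stopifnot(contig_len >= 10000L, gc_fraction >= 0, gc_fraction <= 1,
            snc_rate >= 0, snc_rate <= 1,
            deletion_size_range[1L] <= deletion_size_range[2L],
            mh_range_nhej[1L] <= mh_range_nhej[2L],
            mh_range_mmej[1L] <= mh_range_mmej[2L],
            insertion_len_range[1L] <= insertion_len_range[2L],
            sva_truncation_range[1L] <= sva_truncation_range[2L],
            polyT_len >= 1L, en_motif %in% c("CTTTA", "TTTTA"))
  structure(list(contig_len = as.integer(contig_len),
                 gc_fraction = gc_fraction, seed = as.integer(seed),
                 n_per_mechanism = as.integer(n_per_mechanism),
                 deletion_size_range = as.integer(deletion_size_range),
                 mh_range_nhej = as.integer(mh_range_nhej),
                 mh_range_mmej = as.integer(mh_range_mmej),
                 insertion_len_range = as.integer(insertion_len_range),
                 snc_rate = snc_rate,
                 sva_truncation_range = as.integer(sva_truncation_range),
                 polyT_len = as.integer(polyT_len), en_motif = en_motif,
                 flank_len = as.integer(flank_len)),
            class = "sim_config")
}

.rand_int <- function(lo, hi) if (lo >= hi) as.integer(lo) else
  sample(seq.int(lo, hi), 1L)

#' Generate a reference contig with planted features
#'
#' Random contig at the target GC with planted L1 endonuclease consensus
#' sites and a few labeled gene-proxy intervals. Alu pairs are planted
#' separately ([plant_alu_pair()]).
#'
#' @param cfg A [sim_config()].
#' @param seed Seed for this contig (default `cfg$seed`).
#' @param contig_id Contig name.
#' @return List with class `sim_reference`: `record` (a
#'   [sequence_record()]), `features` (data frame kind/start/end/strand/
#'   label/identity/pair_id/cleavage), `cfg`.
#' @export
make_reference <- function(cfg, seed = cfg$seed, contig_id = "sim_contig") {
  if (cfg$contig_len < 10000L) stop("contig_len must be >= 10 kb")
  set.seed(seed)
  seq <- random_dna(cfg$contig_len, cfg$gc_fraction)
  n <- cfg$contig_len
  feats <- list()
  # endonuclease consensus sites: one early (guaranteed room for a
  # downstream deletion) plus one per ~5 kb
  en_pos <- unique(c(1000L + .rand_int(0L, 500L),
                     sort(sample(seq.int(600L, n - 600L),
                                 max(2L, n %/% 5000L)))))
  for (p in en_pos) {
    seq <- splice_seq(seq, p, p + 4L, cfg$en_motif)
    feats[[length(feats) + 1L]] <- data.frame(
      kind = "l1_en", start = p, end = p + 4L, strand = "+",
      label = cfg$en_motif, identity = NA_real_, pair_id = NA_character_,
      cleavage = p + 3L, stringsAsFactors = FALSE)
  }
  # gene proxies (annotation plumbing for labeling operations)
  bounds <- round(seq(1L, n, length.out = 5L))
  for (g in 1:3) {
    feats[[length(feats) + 1L]] <- data.frame(
      kind = "gene", start = bounds[g] + 100L, end = bounds[g + 1L] - 100L,
      strand = "+", label = paste0("GENE_", LETTERS[g]),
      identity = NA_real_, pair_id = NA_character_, cleavage = NA_integer_,
      stringsAsFactors = FALSE)
  }
  structure(list(record = sequence_record(contig_id, seq),
                 features = do.call(rbind, feats), cfg = cfg),
            class = "sim_reference")
}

#' Plant a diverged repeat (Alu-proxy) pair
#'
#' Writes two copies of a random Alu-sized arm into the contig, diverged
#' by substitution only to the requested pairwise identity. An optional
#' `exact_block` of arm offsets is kept identical between the copies (and
#' its edges forced to diverge), which lets a deletion junction be placed
#' inside a perfectly matching homology block.
#'
#' @param ref A `sim_reference`.
#' @param positions Arm start positions `c(start1, start2)` on the contig.
#' @param identity Target pairwise identity percent (70-100).
#' @param arm_len Arm length in bp (100-350; default 300).
#' @param orientation "direct" (same strand) or "inverted" (second copy
#'   reverse-complemented).
#' @param exact_block Optional `c(lo, hi)` arm offsets kept identical.
#' @param pair_id Feature pair identifier.
#' @return The modified `sim_reference`; the two planted arms appear in
#'   `$features` with kind "alu", the realized identity and shared
#'   `pair_id`.
#' @export
plant_alu_pair <- function(ref, positions, identity = 84, arm_len = 300L,
                           orientation = c("direct", "inverted"),
                           exact_block = NULL, pair_id = "alu_pair_1") {
  orientation <- match.arg(orientation)
  stopifnot(inherits(ref, "sim_reference"), length(positions) == 2L,
            arm_len >= 100L, arm_len <= 350L,
            identity >= 70, identity <= 100)
  p1 <- as.integer(positions[1L]); p2 <- as.integer(positions[2L])
  if (p1 > p2) stop("positions must be ordered")
  if (p1 + arm_len > p2) stop("overlapping arm positions")
  n <- nchar(ref$record$seq)
  if (p1 < 1L || p2 + arm_len - 1L > n) stop("arm outside contig")
  arm <- seq_chars(random_dna(arm_len, 0.55))
  n_sub <- round(arm_len * (100 - identity) / 100)
  protected <- integer(0)
  if (!is.null(exact_block)) {
    stopifnot(exact_block[1L] >= 1L, exact_block[2L] <= arm_len)
    protected <- exact_block[1L]:exact_block[2L]
  }
  candidates <- setdiff(seq_len(arm_len), protected)
  if (n_sub > length(candidates)) stop("identity too low for exact_block size")
  arm2 <- arm
  sub_at <- if (n_sub > 0L) sample(candidates, n_sub) else integer(0)
  # force divergence at the block edges so the exact block is maximal
  if (length(protected)) {
    edges <- intersect(c(min(protected) - 1L, max(protected) + 1L),
                       seq_len(arm_len))
    sub_at <- union(sub_at, edges)
    sub_at <- utils::head(sub_at[order(!sub_at %in% edges)], max(n_sub,
                                                                 length(edges)))
  }
  for (i in sub_at) {
    arm2[i] <- sample(setdiff(c("A", "C", "G", "T"), arm[i]), 1L)
  }
  realized <- 100 * (arm_len - length(sub_at)) / arm_len
  copy2 <- if (orientation == "inverted") {
    seq_chars(revcomp(chars_seq(arm2)))
  } else arm2
  seq <- ref$record$seq
  seq <- splice_seq(seq, p1, p1 + arm_len - 1L, chars_seq(arm))
  seq <- splice_seq(seq, p2, p2 + arm_len - 1L, chars_seq(copy2))
  ref$record$seq <- seq
  add <- data.frame(
    kind = "alu", start = c(p1, p2), end = c(p1, p2) + arm_len - 1L,
    strand = c("+", if (orientation == "inverted") "-" else "+"),
    label = c("AluSyn_a", "AluSyn_b"), identity = realized,
    pair_id = pair_id, cleavage = NA_integer_, stringsAsFactors = FALSE)
  ref$features <- rbind(ref$features, add)
  ref
}

# assemble junction and flank records plus a truth row; all coordinates
# leftmost-aligned. `prox_end` = rightmost possible end of the retained
# proximal segment; `dist_lo` = leftmost possible start of the retained
# distal segment; `mh` the planted tract length.
.emit_junction <- function(jid, mechanism, ref, prox_end, dist_lo, mh,
                           insertion = NULL, snc_plan = NULL,
                           extra = list()) {
  cfg <- ref$cfg
  fl <- cfg$flank_len
  seq <- ref$record$seq
  P <- substr(seq, prox_end - fl + 1L, prox_end)
  D <- substr(seq, dist_lo, dist_lo + fl - 1L)
  left <- seq_chars(P)
  right <- seq_chars(substr(D, mh + 1L, fl))
  sncs <- character(0)
  if (!is.null(snc_plan) && nrow(snc_plan)) {
    for (i in seq_len(nrow(snc_plan))) {
      side <- snc_plan$side[i]; off <- snc_plan$offset[i]
      if (side == "proximal") {
        idx <- fl + off + 1L           # off in [-fl, -1]
        ref_b <- left[idx]
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref_b), 1L)
        left[idx] <- alt
      } else {
        idx <- off - mh                # off in [mh+1, fl]
        ref_b <- right[idx]
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref_b), 1L)
        right[idx] <- alt
      }
      sncs <- c(sncs, sprintf("%s:%d:%s>%s", side, off, ref_b, alt))
    }
  }
  junction <- paste0(chars_seq(left),
                     if (is.null(insertion)) "" else insertion,
                     chars_seq(right))
  # leftmost deleted range: first deleted base follows the proximal
  # retained segment shortened by the tract
  prox_bp <- prox_end - mh + 1L
  dist_bp <- dist_lo - 1L
  truth <- list(
    junction_id = jid, mechanism = mechanism, contig = ref$record$id,
    proximal_bp = prox_bp, distal_bp = dist_bp,
    size = dist_bp - prox_bp + 1L,
    planted_mh_len = if (is.null(insertion)) mh else 0L,
    # with an insertion the flank-overlap word is whatever the emitted
    # flanks actually share (chance can extend the planted word)
    flank_mh = if (is.null(insertion)) mh else .flank_overlap_mh(P, D),
    planted_insertion = if (is.null(insertion)) NA_character_ else insertion,
    n_sncs = length(sncs),
    sncs = if (length(sncs)) paste(sncs, collapse = ",") else NA_character_,
    flank_prox_start = prox_end - fl + 1L,
    flank_dist_start = dist_lo,
    template_side = NA_character_, template_offset = NA_integer_,
    template_strand = NA_character_,
    sine_identity = NA_real_, sine_alignment_len = NA_integer_,
    sva_source = NA_character_, sva_truncation = NA_integer_,
    polyt_len = NA_integer_, en_cleavage_pos = NA_integer_
  )
  if (length(extra)) truth <- utils::modifyList(truth, extra)
  list(junction = sequence_record(jid, junction),
       prox_flank = sequence_record(paste0(jid, "__prox"), P),
       dist_flank = sequence_record(paste0(jid, "__dist"), D),
       truth = truth)
}

# plant the microhomology word: the first `mh` bases of the leftmost
# retained distal segment are overwritten with the last `mh` retained
# proximal bases, so both emitted flanks carry the tract once
.plant_mh <- function(ref, prox_end, dist_lo, mh) {
  if (mh == 0L) return(ref)
  word <- substr(ref$record$seq, prox_end - mh + 1L, prox_end)
  ref$record$seq <- splice_seq(ref$record$seq, dist_lo, dist_lo + mh - 1L,
                               word)
  ref
}

#' Simulate one deletion junction (non-SVA mechanisms)
#'
#' Builds a deletion junction with the signature of the requested
#' mechanism:
#' * `NHEJ` - join with 0-4 bp microhomology, no insertion, no SNC.
#' * `NHEJ_RBM` - short microhomology plus replication evidence: either a
#'   9-11 bp insertion copied (either strand) from within the retained
#'   flanks, or 1-3 single nucleotide changes within 150 bp of the
#'   junction (or both, see `snc_rate`).
#' * `MMEJ_RBM` - 6-52 bp microhomology; the junction sits inside a
#'   planted exact-match pair of that length.
#' * `ALU_NAHR_MMEJ_RBM` - breakpoints inside a planted direct Alu-proxy
#'   pair, junction within an exact homology block of the pair.
#'
#' @param ref A `sim_reference` (fresh per junction; the function plants
#'   the sequence features it needs and records them).
#' @param cfg A [sim_config()] (defaults to `ref$cfg`).
#' @param mechanism One of NHEJ, NHEJ_RBM, MMEJ_RBM, ALU_NAHR_MMEJ_RBM.
#' @param junction_id Identifier for the emitted records.
#' @return List: `junction`, `prox_flank`, `dist_flank`
#'   ([sequence_record()]s), `truth` (named list), `ref` (contig after
#'   planting).
#' @export
simulate_deletion <- function(ref, cfg = ref$cfg, mechanism,
                              junction_id = "J001") {
  mechanism <- mechanism_call(mechanism)
  if (mechanism == "SVA_INSERTION") {
    stop("use simulate_sva_tprt_deletion() for SVA insertion junctions")
  }
  fl <- cfg$flank_len
  n <- nchar(ref$record$seq)
  margin <- fl + 400L
  size <- .rand_int(cfg$deletion_size_range[1L],
                    min(cfg$deletion_size_range[2L], n - 2L * margin - 10L))
  if (size < 100L) stop("contig too short for the configured deletion size")
  extra <- list()
  if (mechanism == "ALU_NAHR_MMEJ_RBM") {
    arm <- 300L
    w <- .rand_int(6L, 30L)
    b1 <- .rand_int(40L, arm - w - 40L)
    b2 <- b1 + w - 1L
    c1 <- .rand_int(margin, margin + 200L)
    c2 <- c1 + size
    if (c2 + arm + fl > n) stop("contig lacks room for the Alu pair")
    ident <- round(stats::runif(1L, 78, 90))
    ref <- plant_alu_pair(ref, c(c1, c2), identity = ident, arm_len = arm,
                          orientation = "direct",
                          exact_block = c(b1, b2),
                          pair_id = paste0(junction_id, "_alu"))
    planted <- ref$features[ref$features$pair_id ==
                              paste0(junction_id, "_alu"), ]
    prox_end <- c1 + b2 - 1L       # rightmost retained proximal base
    dist_lo <- c2 + b1 - 1L        # leftmost retained distal base
    extra <- list(sine_identity = planted$identity[1L],
                  sine_alignment_len = arm)
    return(c(.emit_junction(junction_id, mechanism, ref, prox_end, dist_lo,
                            mh = w, extra = extra),
             list(ref = ref)))
  }
  prox_end <- .rand_int(margin, n - size - margin)   # last retained (rightmost)
  dist_lo <- prox_end + size + 1L                    # leftmost retained distal
  if (mechanism == "NHEJ") {
    mh <- .rand_int(cfg$mh_range_nhej[1L], cfg$mh_range_nhej[2L])
    ref <- .plant_mh(ref, prox_end, dist_lo, mh)
    return(c(.emit_junction(junction_id, mechanism, ref, prox_end, dist_lo,
                            mh = mh),
             list(ref = ref)))
  }
  if (mechanism == "MMEJ_RBM") {
    mh <- .rand_int(cfg$mh_range_mmej[1L], cfg$mh_range_mmej[2L])
    ref <- .plant_mh(ref, prox_end, dist_lo, mh)
    ref$features <- rbind(ref$features, data.frame(
      kind = "repeat_pair", start = c(prox_end - mh + 1L, dist_lo),
      end = c(prox_end, dist_lo + mh - 1L), strand = "+",
      label = "mmej_exact_pair", identity = 100,
      pair_id = paste0(junction_id, "_mh"), cleavage = NA_integer_,
      stringsAsFactors = FALSE))
    return(c(.emit_junction(junction_id, mechanism, ref, prox_end, dist_lo,
                            mh = mh),
             list(ref = ref)))
  }
  # NHEJ_RBM: short (0-2 bp) flank overlap plus replication evidence
  mh <- .rand_int(0L, min(2L, cfg$mh_range_nhej[2L]))
  ref <- .plant_mh(ref, prox_end, dist_lo, mh)
  seq <- ref$record$seq
  with_insertion <- stats::runif(1L) < 0.5
  insertion <- NULL
  if (with_insertion) {
    ins_len <- .rand_int(cfg$insertion_len_range[1L],
                         cfg$insertion_len_range[2L])
    for (try in 1:60) {
      side <- sample(c("proximal", "distal"), 1L)
      strand <- sample(c("+", "-"), 1L)
      if (side == "proximal") {
        off <- .rand_int(-(fl - ins_len), -ins_len)   # template start offset
        tpl_start <- prox_end + off + 1L
      } else {
        off <- .rand_int(1L, fl - ins_len + 1L)
        tpl_start <- dist_lo + off - 1L
      }
      tpl <- substr(seq, tpl_start, tpl_start + ins_len - 1L)
      cand <- if (strand == "+") tpl else revcomp(tpl)
      # guards: the insertion must not merge into either anchor
      last_ok <- mh == 0L ||
        substr(cand, ins_len, ins_len) != substr(seq, dist_lo - 1L + mh,
                                                 dist_lo - 1L + mh)
      dist_first <- substr(seq, dist_lo + mh, dist_lo + mh)
      if (last_ok && substr(cand, ins_len, ins_len) != dist_first &&
          !grepl("N", cand, fixed = TRUE)) {
        insertion <- cand
        extra <- list(template_side = side, template_offset = off,
                      template_strand = strand)
        break
      }
    }
    if (is.null(insertion)) with_insertion <- FALSE
  }
  snc_plan <- NULL
  if (!with_insertion || stats::runif(1L) < cfg$snc_rate) {
    k <- .rand_int(1L, 3L)
    offs <- sort(sample(seq.int(20L, 150L, by = 13L), k))
    sides <- sample(c("proximal", "distal"), k, replace = TRUE)
    snc_plan <- data.frame(
      side = sides,
      offset = ifelse(sides == "proximal", -offs, offs + mh),
      stringsAsFactors = FALSE)
  }
  c(.emit_junction(junction_id, "NHEJ_RBM", ref, prox_end, dist_lo, mh,
                   insertion = insertion, snc_plan = snc_plan,
                   extra = if (with_insertion) extra else list()),
    list(ref = ref))
}

#' Simulate an SVA insertion-associated deletion junction (TPRT model)
#'
#' Models target-primed reverse transcription at an L1 endonuclease
#' consensus site resolved by ligation to a distal double strand break:
#' the proximal flank ends at the endonuclease cleavage point (between the
#' T and A of [C/T]TTT/A), followed by a polyT tract, the 5'-truncated
#' reverse-transcribed SVA copy, and the distal flank. No target site
#' duplication is formed: the deletion replaces the local downstream
#' repair.
#'
#' @param ref A `sim_reference` containing at least one planted
#'   endonuclease consensus site with room for the deletion.
#' @param source An [sva_source()] model.
#' @param cfg A [sim_config()] (defaults to `ref$cfg`).
#' @param junction_id Identifier.
#' @param truncation 5' truncation offset in bp, or `NULL` to draw from
#'   `cfg$sva_truncation_range` (capped so VNTR tail, SINE-R and polyA
#'   survive).
#' @return As [simulate_deletion()]; `truth` additionally carries the
#'   source id, truncation offset, polyT length, cleavage position and
#'   component spans on the junction (`sva_components`).
#' @export
simulate_sva_tprt_deletion <- function(ref, source, cfg = ref$cfg,
                                       junction_id = "J001",
                                       truncation = NULL) {
  stopifnot(inherits(source, "sva_source"))
  fl <- cfg$flank_len
  n <- nchar(ref$record$seq)
  en <- ref$features[ref$features$kind == "l1_en", , drop = FALSE]
  if (nrow(en) == 0L) stop("contig lacks a planted endonuclease site")
  ok <- en$cleavage >= fl + 1L &
    en$cleavage + cfg$deletion_size_range[1L] + fl + 10L <= n
  if (!any(ok)) stop("no endonuclease site with room for the deletion")
  en <- en[ok, , drop = FALSE]
  e <- en$cleavage[sample.int(nrow(en), 1L)]
  size <- .rand_int(cfg$deletion_size_range[1L],
                    min(cfg$deletion_size_range[2L],
                        n - e - fl - 10L))
  sine_r <- source$components[source$components$name == "SINE_R", ]
  trunc_cap <- max(0L, sine_r$start - 200L)
  if (is.null(truncation)) {
    truncation <- .rand_int(cfg$sva_truncation_range[1L],
                            min(cfg$sva_truncation_range[2L], trunc_cap))
  }
  if (truncation >= source$total_len) {
    stop("truncation exceeds source length")
  }
  copy <- substr(source$seq, truncation + 1L, source$total_len)
  polyt <- strrep("T", cfg$polyT_len)
  prox_bp <- e + 1L                     # first deleted base (the A)
  dist_bp <- e + size
  seqref <- ref$record$seq
  P <- substr(seqref, e - fl + 1L, e)
  D <- substr(seqref, dist_bp + 1L, dist_bp + fl)
  junction <- paste0(P, polyt, copy, D)
  # component spans of the inserted copy on the junction
  ins_start <- fl + cfg$polyT_len + 1L
  comp <- source$components
  comp <- comp[comp$end > truncation, , drop = FALSE]
  comp$start <- pmax(comp$start, truncation + 1L) - truncation +
    ins_start - 1L
  comp$end <- comp$end - truncation + ins_start - 1L
  truth <- list(
    junction_id = junction_id, mechanism = "SVA_INSERTION",
    contig = ref$record$id,
    proximal_bp = prox_bp, distal_bp = dist_bp,
    size = dist_bp - prox_bp + 1L,
    planted_mh_len = 0L, flank_mh = 0L,
    planted_insertion = NA_character_,
    n_sncs = 0L, sncs = NA_character_,
    flank_prox_start = e - fl + 1L, flank_dist_start = dist_bp + 1L,
    template_side = NA_character_, template_offset = NA_integer_,
    template_strand = NA_character_,
    sine_identity = NA_real_, sine_alignment_len = NA_integer_,
    sva_source = source$source_id, sva_truncation = truncation,
    polyt_len = cfg$polyT_len, en_cleavage_pos = e
  )
  list(junction = sequence_record(junction_id, junction),
       prox_flank = sequence_record(paste0(junction_id, "__prox"), P),
       dist_flank = sequence_record(paste0(junction_id, "__dist"), D),
       truth = truth,
       sva_components = comp,
       ref = ref)
}

#' Build a full synthetic cohort
#'
#' Generates `cfg$n_per_mechanism` junctions for each of the five
#' mechanisms, each on its own reference contig, with ground-truth table
#' and planted-feature annotation. Fully deterministic under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param sources SVA source library (default [sva_source_library()] built
#'   from `cfg$seed`).
#' @return List with class `sim_cohort`: `junctions`, `flanks` (lists of
#'   [sequence_record()]s), `truth` (data frame, one row per junction),
#'   `features` (planted-feature annotation with junction_id), `sva_components`
#'   (per-junction component spans), `sources`, `cfg`.
#' @export
build_cohort <- function(cfg = sim_config(), sources = NULL) {
  if (is.null(sources)) {
    sources <- sva_source_library(seed = (cfg$seed * 7L + 11L) %% .Machine$integer.max)
  }
  mechs <- mechanism_levels
  junctions <- list(); flanks <- list(); truth_rows <- list()
  feat_rows <- list(); comp_rows <- list()
  k <- 0L
  for (mech in mechs) {
    for (i in seq_len(cfg$n_per_mechanism)) {
      k <- k + 1L
      jid <- sprintf("J%03d_%s", k, mech)
      sub_seed <- (cfg$seed * 1000003L + k) %% .Machine$integer.max
      ref <- make_reference(cfg, seed = sub_seed, contig_id = jid)
      sim <- if (mech == "SVA_INSERTION") {
        src <- sources[[1L + (i %% length(sources))]]
        simulate_sva_tprt_deletion(ref, src, cfg, junction_id = jid)
      } else {
        simulate_deletion(ref, cfg, mech, junction_id = jid)
      }
      junctions[[jid]] <- sim$junction
      flanks[[paste0(jid, "__prox")]] <- sim$prox_flank
      flanks[[paste0(jid, "__dist")]] <- sim$dist_flank
      truth_rows[[jid]] <- as.data.frame(sim$truth,
                                         stringsAsFactors = FALSE)
      f <- sim$ref$features
      f$junction_id <- jid
      feat_rows[[jid]] <- f
      if (!is.null(sim$sva_components)) {
        cc <- sim$sva_components
        cc$junction_id <- jid
        comp_rows[[jid]] <- cc
      }
    }
  }
  structure(list(
    junctions = junctions, flanks = flanks,
    truth = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))),
    features = do.call(rbind, c(feat_rows, list(make.row.names = FALSE))),
    sva_components = if (length(comp_rows))
      do.call(rbind, c(comp_rows, list(make.row.names = FALSE))) else NULL,
    sources = sources, cfg = cfg
  ), class = "sim_cohort")
}

#' Write a cohort to disk
#'
#' Emits `junctions.fasta`, `flanks.fasta`, `truth.tsv` and
#' `planted_features.tsv` into a directory.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(unname(cohort$junctions), file.path(dir, "junctions.fasta"))
  write_fasta(unname(cohort$flanks), file.path(dir, "flanks.fasta"))
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$features, file.path(dir, "planted_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
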