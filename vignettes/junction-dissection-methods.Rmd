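---
title: "Dissecting deletion breakpoint junctions: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting deletion breakpoint junctions: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svabreak)
```

## The problem

Large genomic deletions with non-recurrent breakpoints — such as the
atypical deletions of the NF1 region at 17q11.2 — arise from a
heterogeneous set of mutational processes. The breakpoint junction itself
is the primary evidence: blunt or short-microhomology joins point to
non-homologous end joining (NHEJ); microhomologies of six or more base
pairs are the prerequisite of microhomology-mediated end joining (MMEJ);
short templated microinsertions and clustered single nucleotide changes
(SNCs) near the junction betray replication-based mechanisms (fork
stalling with template switching, microhomology-mediated break-induced
replication); junctions inside a pair of directly oriented, highly
similar Alu elements suggest Alu-mediated nonallelic homologous
recombination; and a 5'-truncated SVA retrotransposon at the junction,
with L1-endonuclease cleavage context and polyT tract but no target site
duplication, marks an insertion-associated deletion resolved by ligation
to a distal double strand break.

`svabreak` implements each of these readouts as a testable operation,
plus a synthetic-data generator that plants every signature with known
ground truth, so the whole pipeline can be validated end to end without
any external genome sequence.

## Junction dissection model

A junction is dissected against two reference flanks with a fixed
convention:

* the **proximal flank** is the retained reference sequence whose first
  base coincides with the first junction base, extended up to the
  *rightmost* reconstruction-equivalent breakpoint;
* the **distal flank** starts at the *leftmost* reconstruction-equivalent
  breakpoint and its last base coincides with the last junction base.

With maximal exact anchors `a` (junction prefix onto the proximal flank)
and `b` (junction suffix onto the distal flank) and junction length `n`:

* `a + b - n > 0` is the **microhomology** length — the tract at the
  transition explainable by both flanks; `a + b = n` is a blunt join;
* `a + b < n` leaves a middle segment explained by neither flank: a
  **microinsertion** (its flank-overlap word, if any, is reported as
  `flank_mh` metadata rather than as microhomology — one call never
  carries both, since the table convention of reporting a microhomology
  *and* an insertion is ambiguous about how the microhomology is
  measured).

Matching is exact by design: reported microhomology lengths are integers
and exactness keeps the brute-force oracle trivial. Breakpoints inside a
microhomology tract are inherently ambiguous; the package always reports
the **leftmost** placement (tract assigned to the distal side). Every
alternative placement within the tract reconstructs the junction
byte-for-byte, which the test suite asserts.

### Tolerating single nucleotide changes

Replication-based junctions carry SNCs within ~150 bp of the breakpoint,
which would truncate exact anchors. `characterize_junction()` therefore
extends anchors through isolated substitutions: a mismatch is accepted
only when followed by at least `match_run = 8` matching bases, up to
`max_snc = 5` per side. Accepted mismatches are then re-screened
position-wise against the reference flank (`detect_sncs()`, window 150
bp, with a known-variant exclusion list standing in for catalogued
polymorphisms). The pure `compute_microhomology()` /
`detect_insertion()` operations stay strictly exact; only the composite
caller is tolerant.

### Templated insertion search

Microinsertions are scanned against ±300 bp of sequence context around
either breakpoint, on both strands, with ≤1 mismatch for insertions up
to 11 bp (10% of length beyond that). The 300 bp window covers the
150 bp SNC window plus margin; the tolerance operationalizes "homologous
to nearby sequence" which is otherwise unquantified. Insertions longer
than 100 bp are not template-searched — segments of that size are
candidate retroelement insertions and go to the SVA annotation route.

## Mechanism classification

`classify_mechanism()` maps a feature vector to one call by fixed
precedence:

1. SVA element detected → `SVA_INSERTION`
2. microhomology ≥ 6 bp *and* a directly oriented SINE pair with ≥ 75%
   identity over ≥ 100 bp spanning both breakpoints → `ALU_NAHR_MMEJ_RBM`
3. microhomology ≥ 6 bp → `MMEJ_RBM`
4. a templated 1–11 bp insertion, or an SNC near the junction →
   `NHEJ_RBM`
5. otherwise → `NHEJ`

Rationale for the thresholds: the 6 bp MMEJ floor is the integer form of
"microhomology above 5 bp"; the SINE-pair gate (75% / 100 bp) sits just
below the weakest pair given that call in the packaged table (79% in
112 bp), so all three tabulated Alu-pair deletions pass while unrelated
repeat context does not. Compound labels ("NHEJ/RBM",
"Alu-mediated NAHR/MMEJ/RBM") are collapsed to a single enum per call —
the classifier reproduces the primary label deterministically rather
than emitting probabilities. Repeat context that the table itself does
not use for labeling (for example a junction lying within a large
inverted repeat) is reported as annotation, never consumed by the
classifier.

## Repeat and motif scanners

The breakpoint-flank scanners are in-package equivalents of the external
tools usually used for such scans, at their published parameter ranges:

* **Direct repeats**: exact arms 10–150 bp separated by < 10 bp.
* **Inverted repeats**: exact arms 6–150 bp separated by < 100 bp.
* **Large repeats** (`self_align_repeats()`): self-alignment by exact
  11-mer seeds, ungapped X-drop extension, both orientations, reporting
  arms ≥ 151 bp at ≥ 87% identity (the published BLASTN parameters are
  unstated; exact seeds of length 11 detect ≥ 87% arms reliably at this
  scale). Intended for windows of a few tens of kb.
* **L1 endonuclease sites**: every TTTT/A and CTTT/A occurrence, both
  strands by default (strand handling is unstated in the source
  protocol; both-strand scanning is the recorded choice), with the
  cleavage position between the 4th and 5th motif base.
* **Homopolymer tracts**: maximal runs, default minimum 10 bp for a
  "long" polyT (also a recorded choice — no published minimum exists).
* **Pairwise identity**: global affine-gap alignment (match 1, mismatch
  −1, open −2, extend −0.5), identity = matches / alignment columns.

Homopolymer runs ≥ 8 bp are masked before the short-repeat scans;
otherwise polyA/polyT tracts flood the hit lists. Overlapping hits
collapse to maximal arms; arms exceeding the configured maximum are
reported clipped at it. Each scanner is property-tested against a naive
run-enumeration oracle on random ≤ 300 bp inputs, and obeys strand
symmetry and threshold monotonicity.

## SVA model and annotation

A source element is modeled with the canonical component order:
optional 5' transduction, (CCCTCT)n hexamer, ~343 bp Alu-like region,
GC-rich VNTR (tandem unit with light divergence, GC ≥ 0.7), SINE-R,
polyA. The default library emulates the two size classes of highly
active source elements (4,039 bp with a 2,093 bp VNTR at 79% GC, and
2,691 bp without transduction); sequences outside these constraints are
random — the package ships no copyrighted genome sequence, and real
source libraries are supplied by the user as FASTA.

`annotate_sva()` assigns the best source by *local* alignment identity
over the aligned span, not whole-element length — a deliberately chosen
mirror of how a heavily 5'-truncated copy can still show ~99% homology
to its source. Component boundaries map from the source model through
the alignment offset; the VNTR GC and polyA length are measured on the
query. **SINE-R presence is the minimal requirement for an SVA call**:
it is the 3'-most diagnostic component and survives 5' truncation.
Truncation offsets ≤ 50 bp count as full length. Subfamily labels pass
through from the library and are never inferred. A fast exact 25-mer
prefilter skips alignment for queries sharing nothing with a source.

TPRT hallmarks are flagged from the annotated junction: endonuclease
cleavage context (the retained proximal flank of a cleavage-point
breakpoint ends in [C/T]TTT — the consensus A lies on the deleted
side), polyT tract abutting the element start, polyA tail at the element
3' end, and VNTR GC ≥ 0.7. `detect_tsd()` reports the longest exact
boundary word of 5–25 bp; deletion-associated insertions have none by
construction.

## The synthetic-data generator

The generator defines the study conditions for every test. Each
junction gets its own random reference contig (default 20 kb at GC
0.41), a deleted segment of 5–12 kb and 300 bp retained flanks. These
sizes are a deliberate desk-scale model of deletions that span hundreds
of kb to several Mb in vivo: every junction-level signature
(microhomology word, insertion template, SNC offsets, Alu-pair homology
block, TPRT junction structure) is byte-identical to its full-size
counterpart, because none of the dissection operations see anything
beyond the flanks and the junction. What the scaled cohort does *not*
exercise is genome-scale repeat background (segmental duplications,
true Alu density) and alignment ambiguity from diverged flanking
repeats — so passing tests validate the operations and their
composition, not performance on real genomic context.

Mechanism signatures are planted as follows:

* NHEJ: microhomology drawn from 0–4 bp, written so the emitted flanks
  share the tract exactly once; no insertion, no SNC.
* NHEJ_RBM: flank overlap ≤ 2 bp plus either a 9–11 bp insertion copied
  exactly (either strand) from within the retained flanks, or 1–3 SNCs
  planted 20–150 bp from the junction (both, with probability
  `snc_rate = 0.25`, mirroring junctions that show an insertion *and*
  SNCs). Template copies are exact — divergence would only blur the
  recorded ground truth.
* MMEJ_RBM: microhomology 6–52 bp, the junction lying inside a planted
  exact-match pair of that length.
* ALU_NAHR_MMEJ_RBM: a directly oriented 300 bp Alu-proxy pair diverged
  by substitution only to 78–90% identity (substitution-only keeps
  identity accounting exact), with a 6–30 bp identical block around the
  crossover so the junction sits inside the homology.
* SVA_INSERTION: endonuclease nick at a planted CTTT/A site, polyT(40)
  tract, 5'-truncated copy of a library source, ligation to the distal
  flank; no target site duplication, plus-strand insertion only by
  default (both tabulated insertions were plus-strand; minus orientation
  is available via the annotation's orientation handling). The
  truncation offset is uniform over its configured range, capped so the
  VNTR tail, SINE-R and polyA survive — a stand-in, since no empirical
  truncation-length distribution is available (the two characterized
  copies retained 1.7 kb of 4.0 kb and 1.3 kb of 2.69 kb).

Determinism: the master seed derives one sub-seed per junction; a fixed
configuration reproduces byte-identical FASTA and truth tables.

## Numerical and statistical choices

* Coordinates are 1-based inclusive everywhere; deletion size is
  `distal − proximal + 1`, and the same inclusive rule applies to
  breakpoint separations. BED output converts at the file boundary only.
* Control regions given as half-open spans tile exactly (60 kb / 300 bp
  = 200 fragments; 120 kb / 4 kb = 30), with hypothetical breakpoints at
  fragment midpoints.
* The Fisher exact test is the standard two-tailed conditional test:
  sum of hypergeometric probabilities ≤ the observed table's (relative
  tolerance 1e-7). It is computed directly from the hypergeometric mass
  function so tests can cross-check it against both a from-scratch
  combinatorial enumeration and the independent stats implementation.
* kb spans round half-up at one decimal, so a 32,559 bp window prints
  as 32.6 kb.
* Densest-window search scans runs of consecutive sorted coordinates
  (the optimum is always such a run); ties resolve leftmost.

## Known limitations

* Microhomology is exact-match only; diverged homeology at junctions is
  reported as shorter microhomology plus SNCs.
* The SNC-tolerant anchoring assumes isolated substitutions ≥ 8 bp
  apart; denser clusters or indels near the transition produce a
  conservative insertion call instead.
* `annotate_sva()` boundary mapping is offset-based over the local
  alignment; indel-rich copies can shift component boundaries by a few
  bp, and the truncation offset can rag a few bases where the polyT
  tract abuts VNTR-like sequence.
* The inverted-repeat scanner is quadratic in window length and intended
  for breakpoint-flank fragments (≤ ~5 kb), not chromosomes.
* Subfamily assignment, genome-wide retroelement discovery and
  cross-chromosome transduction tracing are out of scope.
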