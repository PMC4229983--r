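# svabreak

Dissection of deletion breakpoint junctions and analysis of SVA
retrotransposon insertion-associated deletions.

## What this is for

Large genomic deletions with non-recurrent breakpoints — the atypical
deletions of the NF1 region at 17q11.2 are the motivating case — are
produced by several distinct mutational processes, and the breakpoint
junction is the evidence that tells them apart. `svabreak` is for
researchers characterizing such junctions from assembled
breakpoint-spanning sequences: it extracts the junction-level features,
calls the underlying mechanism, and provides the statistics used to
describe breakpoint clustering and flanking-sequence enrichment. A
built-in simulator generates junctions with full ground truth for every
mechanism, so the pipeline is testable without any reference genome.

## The model at the core

Given a junction *J* and its proximal/distal reference flanks, maximal
exact anchors of length *a* (prefix) and *b* (suffix) dissect the
junction:

* **microhomology** of length *m* = *a* + *b* − |*J*| when positive — the
  tract explainable by both flanks; breakpoints inside the tract are
  reported leftmost;
* a **microinsertion** *J*[*a*+1 … |*J*|−*b*] when *a* + *b* < |*J*|,
  searched against ±300 bp of breakpoint context (both strands) for a
  templated source;
* **SNCs**: isolated substitutions within 150 bp of the breakpoint,
  tolerated inside the anchors and screened against known variants.

Features map to one mechanism call by precedence:

| call | rule |
|---|---|
| `SVA_INSERTION` | SVA element annotated at the junction |
| `ALU_NAHR_MMEJ_RBM` | *m* ≥ 6 inside a direct SINE pair, ≥ 75% identity over ≥ 100 bp |
| `MMEJ_RBM` | *m* ≥ 6 |
| `NHEJ_RBM` | templated 1–11 bp insertion, or SNC near the junction |
| `NHEJ` | otherwise |

SVA elements (hexamer / Alu-like / GC-rich VNTR / SINE-R / polyA) are
annotated by local alignment against a source library; target-primed
reverse transcription hallmarks (L1-endonuclease [C/T]TTT/A cleavage
context, polyT tract, polyA tail, VNTR GC ≥ 0.7) and the absence of a
target site duplication distinguish insertion-associated deletions.

## Worked example

```r
library(svabreak)

# the packaged 17-deletion breakpoint feature table
recs <- nf1_deletion_fixture()
rep  <- deletion_table_report(recs)
```

```
deletions: 17  (simple: 15, SVA insertion-associated: 2)
mosaic: 10/17 (59%)   proximal breakpoints in SUZ12P: 11
microhomology 1-4 bp: 10   >=6 bp: 4   SNC-positive: 4
densest telomeric 5-breakpoint window: 32.6 kb
```

Ten of the seventeen deletions are mosaic (postzygotic origin), eleven
have centromeric breakpoints inside the SUZ12P pseudogene, and five
telomeric breakpoints crowd into a 32.6 kb window — all recomputed from
the table's coordinate columns, not copied.

Dissecting a junction against its flanks:

```r
characterize_junction("demo", junction = "TTGACGAGCCTA",
                      prox_flank = "TTGACGAG", dist_flank = "AGCCTA",
                      config = list(min_anchor = 3L))
#> <junction_call> demo: mh=2, 0 template hit(s), 0 SNC(s)
```

The `AG` at the transition is explainable by either flank: a 2 bp
microhomology, breakpoints reported leftmost.

End-to-end on simulated data:

```r
res <- run_pipeline(sim_config(seed = 1, n_per_mechanism = 5))
res
#> <pipeline_result> 25 junctions, overall recovery 100.0%
res$summary$tprt_en_site_rate   # 1: every simulated TPRT junction has
res$summary$tprt_polyt_rate     # the cleavage context and polyT tract
```

A command-line wrapper covers the same stages
(`exec/svabreak simulate|characterize|annotate-sva|scan-motifs|classify|cluster|enrich`).

## Layout

* `R/` — data model and I/O, junction dissection, repeat/motif scanners,
  SVA annotation, mechanism classifier, breakpoint statistics, simulator,
  pipeline, CLI.
* `inst/extdata/` — the deletion feature table and a synthetic proxy
  annotation of the surrounding gene region (interval boundaries
  constructed for label consistency, not genome coordinates).
* `vignettes/junction-dissection-methods.Rmd` — the methods vignette:
  models, conventions, parameter rationale, simulator design and
  limitations.
* `tests/testthat/` — unit and property tests with brute-force oracles.
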