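Package: svabreak
Title: Deletion Breakpoint Junction Dissection and SVA
    Insertion-Associated Deletion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to characterize the breakpoint junctions of large genomic
    deletions with non-recurrent breakpoints: microhomology and
    microinsertion dissection against reference flanks, templated-insertion
    source search, detection of breakpoint-flanking single nucleotide
    changes, annotation of composite SVA retrotransposons with
    target-primed reverse transcription hallmarks, repeat and L1
    endonuclease motif scanning, mutational-mechanism classification
    (NHEJ, replication-based, MMEJ, Alu-mediated NAHR, SVA
    insertion-associated), and breakpoint clustering and enrichment
    statistics. A synthetic-data generator simulates deletion junctions
    with known ground truth for every mechanism, including SVA
    insertion-associated deletion by endonuclease nick, reverse
    transcription and ligation to a distal double strand break, so the
    whole pipeline is testable without external genome data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
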