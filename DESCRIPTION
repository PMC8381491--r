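Package: pgscreen
Title: CRISPRi Screen Design and Analysis for Pseudogenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated workflow for pooled CRISPRi fitness screens
    targeting pseudogenes. Assigns transcription start sites (TSSs) from
    CAGE clusters with TIEScore priority, designs sgRNA spacers in
    500-bp promoter windows with a quality filter cascade
    (multi-mapping, N content, poly-T, extreme GC, 4-bp deduplication),
    quantifies pseudogene expression with a uniquely-mappable
    effective-length FPKM, searches PAM-constrained mismatch off-target
    sites, counts screen reads into an sgRNA-by-sample matrix, and
    calls negatively selected hits via control-normalized fold changes
    and permutation-based rank aggregation, with bidirectional-promoter
    and parent/pseudogene off-target confound controls. Includes a
    synthetic fixture generator with known ground truth so every stage
    is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    methods,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
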