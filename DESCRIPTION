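Package: structkit
Title: Desk-Scale Structural Analyses for the Giant E3 Ligase RNF213
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence- and structure-level analyses accompanying the
    characterization of RNF213, the Moyamoya-disease susceptibility factor:
    FoldIndex intrinsic-disorder profiling with composite multi-window plots,
    sum-of-pairs sequence conservation with sliding-window smoothing,
    crosslink mass-spectrometry validation of atomic models (FDR filtering,
    Calpha distance mapping, distance-band satisfaction statistics),
    missense-variant curation with CADD severity binning and domain-clustering
    statistics, least-squares (Kabsch) structure superposition, and
    NADH-coupled ATPase rate extraction under the pseudo-zero-order
    approximation. A synthetic-data module generates toy structures,
    crosslink sets, alignments, mutation tables and assay traces with known
    ground truth so that every stage is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    methods,
    stats,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
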