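Package: afmetrics
Title: Confidence-Filtered Interface Scoring for AlphaFold2 Multimer Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating AlphaFold2 Multimer protein-protein
    interaction screens and structural conservation of protein domains
    across large ortholog panels. Implements confidence-filtered
    inter-chain contact detection, the average-models contact consistency
    score, interface predicted-aligned-error summaries, alignment-anchored
    domain coordinate mapping, ortholog presence/absence curation from
    homology-search hit tables, backbone-dihedral helix detection for
    domain conservation calls, and group-level rank statistics. Includes a
    synthetic fixture generator that emulates AlphaFold2 output files with
    known ground truth, so the full pipeline can be exercised and
    validated without GPU-scale structure prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
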