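Package: rnaidesign
Title: Design and Evaluation of Optimized dsRNA Sequences for RNA Interference
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing double-stranded RNA (dsRNA) regions
    optimized for RNA interference (RNAi), with a focus on insect pest
    control. Every candidate small interfering RNA (siRNA) derived from a
    target transcript is scored for predicted silencing efficacy
    (thermodynamic end asymmetry from nearest-neighbor duplex energies,
    antisense self-folding energy, positional base composition, target-site
    accessibility) and for off-target safety against non-target
    transcriptomes with mismatch-tolerant k-mer matching. A sliding window
    selects the dsRNA region with the best mean score. Companion modules
    map RISC-bound small-RNA reads strand-specifically onto dsRNA
    templates, compare positional nucleotide composition between abundance
    classes, and analyze insect bioassay survival data (log-rank hazard
    ratios, Cox proportional hazards, hazard-ratio regression). Synthetic
    data generators make the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    survival,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
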