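Package: interactomeSize
Title: Interactome Size Estimation from Overlap of Literature-Curated and
    High-Throughput Interaction Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the size of a binary physical protein-protein
    interactome by capture-recapture on the overlap between high-throughput
    (HT) interaction screens and literature-curated (LC) data restricted to
    well-studied proteins. Implements BioGRID-style curation filters (binary
    physical evidence codes, low-throughput publications), a false-discovery
    rate chaining relation that derives every HT dataset's FDR from a single
    reference FDR via pre-2000 LC coverage, true-positive accounting for HT
    and LC datasets, the hypergeometric (Lincoln-Petersen) overlap estimator
    with normal-approximation confidence intervals, study-bias diagnostics,
    and a synthetic-interactome benchmark that validates the bias-correction
    strategy on worlds with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
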