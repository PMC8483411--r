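Package: polypharm
Title: Scoring and Prioritization of Multi-Target Kinase Inhibitor Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evaluation pipeline for crowdsourced polypharmacology challenges:
    rubric-based scoring of candidate compounds from kinase Kd selectivity
    panels (pro-target binding at 10 uM, anti-target avoidance at 30 uM,
    novelty, patentability, drug-likeness and CNS-penetration bonuses),
    chemical-similarity network analysis of submitted structures, an
    eight-category ADME composite score built from published drug-likeness
    rule sets (Lipinski, Ghose, Veber, Egan, Muegge, lead-likeness) and
    structural-alert catalogs (PAINS, Brenk), pIC50 activity-class labeling,
    and a deterministic synthetic-data generator so the full pipeline runs
    without external downloads. Low-level chemistry (SMILES parsing,
    fingerprints, descriptors, SMARTS matching) is backed by Open Babel via
    ChemmineOB.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
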