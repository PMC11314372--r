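Package: PCSkit
Title: Comparative Sequence Analysis of Phytochelatin Synthases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation and comparative analysis of phytochelatin synthase
    (PCS) protein sequences from cyanobacteria and microalgae. Locates the
    catalytic Cys/His/Asp triad, classifies sequences into the "N" (group 1)
    and "E"/"D" (group 2) isoforms by the residue four positions upstream of
    the catalytic cysteine, calls casein-kinase-2 phosphorylation competence
    from the [ST]-X2-[DE] context, computes ProtParam-style physicochemical
    profiles (molecular weight, isoelectric point, charged-residue
    percentages, instability and aliphatic indices), estimates pairwise
    maximum-likelihood distances under the JTT substitution model with
    neighbor-joining trees and bootstrap supports, discovers ungapped motifs
    by ZOOPS expectation maximization, and compares groups with Student's
    t-test after Shapiro-Wilk and Levene checks. A synthetic-data generator
    produces PCS-like scaffolds with known ground truth so the whole pipeline
    is testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    ape,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'PCSkit-package.R'
    'AllClasses.R'
    'align.R'
    'classify.R'
    'constants-jtt.R'
    'constants-physchem.R'
    'motif.R'
    'phylo.R'
    'physchem.R'
    'pipeline.R'
    'seq-io.R'
    'stats.R'
    'synthetic.R'
    'triad.R'
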