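Package: itraqpipe
Title: Isobaric-Tag Reporter Quantification and Treatment-Contrast
    Regulation Calling for Cerebral-Artery Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for four-plex isobaric-tag (iTRAQ) shotgun proteomics
    of rat cerebral arteries after experimental subarachnoid hemorrhage:
    target-decoy q-value estimation and two-stage PSM filtering (1% peptide
    FDR plus a Mascot-style score floor), protein-level log2 reporter ratios
    against a sham reference channel, per-channel median normalization, a
    2-standard-deviation regulation statistic, and the two-criteria contrast
    classification that separates proteins whose hemorrhage-induced change
    is abolished by MEK1/2 inhibition (U0126) from persistently regulated
    ones.  Ships a synthetic PSM generator with known ground truth for
    end-to-end validation, verbatim transcriptions of the study's published
    protein tables, and offline molecular-function and interaction-network
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
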