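Package: alkrepair
Title: Repair-Pathway Crosstalk and Double-Strand Break Formation in
    Alkylated Plasmid DNA
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic modelling of replication-independent double-strand
    break (DSB) formation in alkylated DNA. Implements agent-specific
    alkylation adduct spectra (7mG, 3mA, O6mG for MNU/TMZ-class versus
    MMS-class agents), dose-calibrated Poisson placement of lesions on
    circular duplex plasmids, an in-silico heat/alkali cleavage assay that
    converts N-alkyl adducts to strand breaks and inverts fragment-size
    medians to lesion densities, a Monte Carlo snapshot simulator in which
    base excision repair nicks and mismatch repair excision gaps on opposite
    strands combine into DSBs, quadratic dose-response sweeps and fits, and
    deterministic genome-scale extrapolation calculators (at-risk lesion
    arrangements, DSBs per genome, clinical-dose scaling, conversion rate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
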