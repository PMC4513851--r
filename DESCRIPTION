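Package: pullQuant
Title: Quantification of Affinity-Purification Mass Spectrometry Pull-Downs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a label-free quantification pipeline for
    affinity-purification mass spectrometry (AP-MS) interactome studies:
    target-decoy FDR filtering of peptide-spectrum matches, protein
    abundance factor (PAF) and top-3 peak-area scoring, subtraction of
    mock-bait control background, bait-normalized relative stoichiometry
    across replicate pull-downs, and functional-category composition
    summaries. Ships a seeded synthetic AP-MS data generator (in-silico
    tryptic digestion, Poisson sampling of peptide-spectrum matches,
    injected decoy hits) so that every pipeline stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Proteomics, MassSpectrometry, Software
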