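Package: trmine
Title: Mining and Characterisation of Transcription-Factor-Based Metabolite Biosensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide discovery of metabolite-inducible gene expression
    systems in annotated bacterial genomes. Detects transcriptional regulator
    (TR) genes divergently oriented against catabolic operons, extracts the
    shared intergenic promoter region, and infers the candidate effector
    ligand as the entry compound (primary substrate) of the operon-encoded
    pathway using an EC-number reaction knowledgebase. Also provides the
    quantitative biosensor characterisation workflow: blank correction and
    OD normalisation of plate-reader time courses, extraction of the
    minimal-induction window, Hill dose-response fitting with dynamic range
    and propagated uncertainty, relative-induction cross-reactivity and
    orthogonality screening, and intracellular metabolite concentration from
    pellet extractions. Includes seeded generators for synthetic genomes with
    planted TR-operon systems and simulated plate-reader data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
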