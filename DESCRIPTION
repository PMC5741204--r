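Package: sempfinder
Title: Design of Sensing-Enabling Metabolic Pathways for Whole-Cell Biosensors
Version: 0.1.0
Authors@R: person("Maintainer", "Dev", email = "dev@example.org", role = c("aut", "cre"))
Description: Screens for short (one- or two-step) enzymatic transformations that
    convert a target compound into an effector of a known allosteric
    transcription factor, so that an otherwise undetectable molecule can be
    sensed indirectly by a genetically encoded biosensor. Compounds are encoded
    as molecular signatures (multisets of canonical atomic environments at a
    configurable bond diameter) and reactions as signed fragment differences;
    forward application of a reaction signature to a query compound, followed
    by resolution of the resulting fragment multiset against a knowledge base
    of known compounds, models enzymatic promiscuity. The package ships a
    tabular knowledge-base format, fixture generators for worked case studies
    (cocaine to benzoate; parathion to 4-nitrophenol and nitrite), hashed
    circular fingerprints with Jaccard-Tanimoto similarity for annotating
    detectable endpoints, pathway extraction, and GML/TSV exports plus a
    command-line interface. Structure parsing and normalization are delegated
    to RDKit through a bundled Python helper script.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: Python (>= 3.8) with the rdkit package, on PATH as
    'python' or 'python3'.
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
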