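Package: mappkit
Title: Downstream Analysis of MHC-Associated Peptide Proteomics (MAPPs) Panels
Version: 0.1.0
Authors@R:
    person("MAPPs", "Toolkit Maintainers", email = "mappkit@example.org",
           role = c("aut", "cre"))
Description: Tools for the in-silico tail of MHC-associated peptide
    proteomics (MAPPs) immunogenicity assessment of therapeutic antibodies:
    reading and validating peptide-spectrum-match (PSM) tables, confidence
    tiering by charge-dependent XCorr thresholds, concatenated target-decoy
    false-discovery-rate filtering, mapping of eluted peptides onto heavy and
    light chains with CDR-overlap and uniqueness annotation, nested-set
    (cluster) detection over ragged-termini peptide ladders, donor-panel
    summary metrics (peptide counts, presentation frequencies, percent
    therapeutic peptides, biotransformation donor frequencies, replicate
    concordance), SVG peptide-coverage heat maps, and a fully specified
    synthetic-panel generator with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr
Config/testthat/edition: 3
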