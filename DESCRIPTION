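Package: gospec
Title: Function Specificity Metrics for Gene Ontology Terms
Version: 1.0.0
Authors@R: person("Brennan", "Oakes", email = "boakes@example.org", role = c("aut", "cre"))
Description: Computes four quantitative measures of functional specificity for
    Gene Ontology terms: the number of ancestor terms, the number of offspring
    terms with a log-ratio normalization (Offsp_N), the GO proportion of
    reachable terms, and annotation-derived Information Content (IC). Works on
    any OBO 1.2 ontology together with NCBI gene2go or GAF 2.x annotation
    tables, provides a deterministic generator of GO-like synthetic ontologies
    for testing, a command-line interface producing per-term metric tables,
    and a metric-correlation report.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    optparse,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
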