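Package: editrace
Title: Editing-Outcome Quantification and Repair Kinetics for CRISPR-Cas9 RNP Amplicon Sequencing
Version: 0.1.0
Authors@R: person("editrace", "maintainers", email = "editrace@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying CRISPR-Cas9 ribonucleoprotein editing
    outcomes from amplicon deep sequencing: paired-end read merging and inline
    barcode demultiplexing, global-alignment indel calling with artifact
    filtering, microhomology-based classification of alleles into NHEJ, MMEJ
    and HDR repair pathways, estimation of repair completion kinetics (T50,
    the time to half-maximal frequency) from time-course samples, and
    pattern-dispersion (Gini) and donor-competition statistics. Includes a
    synthetic-data generator that implements a stochastic repair-race model
    (delayed-exponential pathway completion) so the entire pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
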