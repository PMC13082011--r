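Package: mimiscan
Title: Antiviral Antibody Repertoire Breadth and Molecular Mimicry
    Screening for Liver Cancer Serology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links enterovirus/rhinovirus (EV/RV) serology to hepatocellular
    carcinoma (HCC) outcomes. Partitions a phage-display peptide catalog into
    CE1-VP1, non-CE1 VP1 and non-VP1 epitope groups from polyprotein chain
    annotations; computes the antibody repertoire breadth (ARB) statistic, a
    normalized Shannon entropy of epitope binding signals, and CE1
    seroreactivity scores; fits the cohort association analyses (logistic
    diagnosis models, chi-square breadth-category tests, Kaplan-Meier /
    log-rank survival stratification); screens immunoprecipitation-mass-
    spectrometry intensity tables for surface-protein molecular mimics of the
    CE1 epitope by fold-change filtering, surface-proteome cross-referencing
    and BLOSUM62 Smith-Waterman alignment ranking; and scores a 20-gene ADCC
    signature on tumor transcriptomes with NK-infiltration and serostatus
    stratified correlation and survival analyses. A seeded synthetic-data
    generator emulates every input so the full pipeline is testable end to
    end without restricted-access cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    survival,
    car,
    jsonlite,
    yaml,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
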