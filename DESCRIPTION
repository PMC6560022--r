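Package: netmoa
Title: Network Models of Disease and Drug Mechanism of Action for
    Biomarker Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds molecular network models of a disease and of a drug's
    mechanism of action (MoA) on a protein-protein interaction network,
    computes their interference signature (shared nodes and interactions),
    and prioritizes candidate biomarkers by signature membership or network
    proximity combined with prognostic literature evidence. A fold-change
    filter turns probe-level expression data into the deregulated gene set
    that extends the MoA core model. A longitudinal module fits mixed-model
    repeated-measures (MMRM) analyses with unstructured within-subject
    covariance and reports between-arm percentage-difference contrasts,
    change correlations, tertile stratification and associations with
    kidney-function decline. A synthetic-data module generates interactomes,
    expression matrices and trial datasets with known planted truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    nlme,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: NetworkInference, GraphAndNetwork, GeneExpression, Microarray,
    SystemsBiology, BiomedicalInformatics
RoxygenNote: 7.3.3
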