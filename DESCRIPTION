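Package: myeloconn
Title: Myelin-Sensitive Weighting and Comparison of Structural Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Build structural brain connectomes weighted either by number of
    streamlines (NOS) or by the median of a quantitative scalar map (such as
    the longitudinal relaxation rate R1) sampled along streamline bundles;
    pool subjects into group-consensus networks; and compare the two edge
    weightings through strength centrality, standard-deviation hub criteria,
    multi-resolution Louvain modularity with consensus clustering and z-Rand
    partition stability, and rank-difference z-score analysis across
    functional and cytoarchitectonic node classes. Includes a synthetic
    phantom generator producing cohorts of connectomes with planted modular
    structure and, optionally, full phantom geometry (parcellation volume,
    scalar volume, streamline tractogram) with known ground truth, plus
    readers and writers for TCK/TRK tractograms, NIfTI volumes, and CSV
    connectivity matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
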