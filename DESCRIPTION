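Package: confens
Title: Conformational Ensemble Analysis of Predicted Protein Structure Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-prediction analysis of protein conformational ensembles:
    mean-energy filtering of structure decoys, hierarchical clustering on
    pairwise backbone RMSD with elbow-based selection of the cluster count,
    lowest-energy centroid extraction, and ensemble characterization by
    per-residue RMSF, Cartesian principal component analysis with
    cross-ensemble projection and density overlap, hinge aperture-angle and
    inter-domain distance descriptors, reference-based conformer population
    fractions, and ensemble spread. Includes a ground-truthed synthetic
    generator of two-state hinge-bending ensembles with double-well energies
    and mean-reverting pseudo-trajectories for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
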