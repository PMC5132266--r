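Package: cholmap
Title: Mapping Lipid Interaction Sites on Membrane Proteins from
    Coarse-Grained Trajectories
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to locate and characterize specific lipid (notably
    cholesterol) interaction sites on membrane proteins from
    coarse-grained molecular dynamics trajectories.  The protocol couples
    maximum occupancy time statistics (per-residue longest
    single-molecule contact durations, merged across replicate data-sets
    by Kruskal-Wallis testing with iterative leave-one-out, and screened
    for Tukey-fence outliers) with a voxelized spatial density
    probability function of lipid beads around the fitted protein.
    Outliers matched to density hotspots reproducible across systems
    define ranked interaction sites, which are further characterized by
    hysteretic dual-RMSD residence-time event detection, binding-mode
    clustering, lipid-species selectivity, and CRAC/CARC
    cholesterol-recognition motif scanning.  A synthetic trajectory
    generator with planted sites and known ground truth supports
    validation and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    bio3d,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'cholmap-package.R'
    'contacts.R'
    'density.R'
    'fit.R'
    'io-topology.R'
    'io-trajectory.R'
    'motifs.R'
    'pbc.R'
    'pipeline.R'
    'sites.R'
    'stats.R'
    'synthetic.R'
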