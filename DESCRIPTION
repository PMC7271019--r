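Package: rcbp
Title: Regional Connectivity-Based Parcellation of Brain Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A workflow for regional connectivity-based parcellation (rCBP)
    of a brain region of interest. Voxels of a binary ROI mask are clustered
    by the similarity of their connectivity fingerprints to a set of target
    voxels, derived either from resting-state BOLD time series (Pearson
    correlation, optionally smoothed, nuisance-regressed, band-pass filtered
    and Fisher-Z transformed) or from precomputed tractography streamline
    counts (densified and cube-root transformed). Individual parcellations
    for a range of cluster counts are aggregated into a group parcellation
    via a Hamming-distance hierarchical reference, optimal permutation
    relabeling and per-voxel mode consensus. Internal cluster-validity
    indices (Silhouette, Calinski-Harabasz, Davies-Bouldin), partition
    similarity scores (adjusted Rand index, adjusted mutual information,
    V-measure), cophenetic correlation and reference-image comparison
    support the evaluation of the resulting parcellations. A synthetic
    cohort generator with planted parcellations makes the whole pipeline
    testable without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    yaml,
    signal,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    parallel,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    mclust,
    optparse
Config/testthat/edition: 3
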