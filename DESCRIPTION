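Package: imcn
Title: Individual Morphological Covariance Networks from Structural MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and group-level analysis of individual (single
    subject) morphological covariance networks from gray-matter volume maps.
    Regional gray-matter value distributions are estimated by Gaussian kernel
    density estimation and compared between all region pairs with a
    symmetrised Kullback-Leibler divergence, mapped to a similarity in (0,1];
    sparsity-thresholded binary graphs are characterised with standard
    graph-theory measures (clustering, path length, global and local
    efficiency, assortativity, modularity, nodal degree and betweenness) and
    small-world normalisation against degree-preserving rewired null models.
    The package also provides voxel-based morphometry group statistics
    (voxelwise ANCOVA, false-discovery-rate and cluster-extent thresholding,
    post-hoc pooled t-tests), clinical correlation analyses, a synthetic
    three-group cohort generator with known ground truth for validation, and
    a file-based pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
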