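Package: hetindex
Title: Single-Parameter H Index and GLCM Texture Features for Intratumor
    Heterogeneity in FDG-PET SUV Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies intratumor heterogeneity from voxel-wise standardized
    uptake value (SUV) distributions in 3D FDG-PET volumes. Implements a
    signed, dimensionless H index that sums absolute SUV differences between
    neighbouring tumor voxels, weighted by each voxel's distance from the
    SUV-weighted tumor centroid, with a sign encoding descending (+) versus
    ascending (-) SUV from centre to periphery. Also provides the 3D
    gray-level co-occurrence matrix (GLCM) over all 26 nearest-neighbour
    offsets and the Energy, Contrast, Local Homogeneity and Entropy texture
    features it is benchmarked against, threshold-based tumor segmentation,
    deterministic spherical and 2D digital lesion phantoms for validation,
    NIfTI volume input/output, phantom parameter sweeps and a feature-versus-
    outcome correlation utility.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
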