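Package: skullflat
Title: Disk Harmonic Flattening of Cranial CT Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts a watertight outer-skull surface from head CT volumes
    (Hounsfield-unit voxels), partitions it into four simply connected
    hemispheric patches (lower, upper, frontal, occipital), flattens each
    patch to the unit disk by a discrete harmonic map with circle-mapped
    Dirichlet boundary conditions on the cotangent Laplacian, builds
    depth-indexed subsurface layer stacks along inward vertex normals, and
    renders maximum/average intensity projections of the flattened layers.
    Per-facet angle and area distortion metrics quantify the
    quasi-conformality of the mapping. Includes a synthetic head-CT phantom
    generator with known geometry and defects (fracture slits, sutures, vein
    channels) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    igraph,
    RNifti,
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
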