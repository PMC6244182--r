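Package: BreastPhantom
Title: MRI-Derived Anthropomorphic Numerical Breast Phantoms for
    Microwave Imaging Simulation
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs anatomically structured numerical breast models
    from 3D breast MRI volumes for microwave imaging simulation. The
    pipeline reads DICOM slice series (or synthetic volumes with ground
    truth generated by the package), denoises the stack by principal
    component analysis, delineates the breast region by threshold-based
    surface detection along three orthogonal planes, segments skin, fat
    and fibroglandular tissue with configurable sub-clustering of the
    fibroglandular class, assigns frequency-dependent dielectric
    properties through a linear intensity-to-property mapping onto
    single-pole Debye parameter curves at three contrast levels, computes
    breast density and the four-class radiological classification, embeds
    parametric tumour inclusions, and exports the resulting models as STL
    surface meshes, raw voxel grids, HDF5 model containers and XML
    property files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    rhdf5,
    xml2,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: ImageProcessing, Segmentation, Classification
RoxygenNote: 7.3.3
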