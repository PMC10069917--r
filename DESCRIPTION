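Package: specpcd
Title: Illumination-Corrected 3D Multispectral Point Clouds of Plants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds 3D multispectral point clouds of plants from paired
    close-range depth (RGB-D) and snapshot spectral images. Implements
    coarse-to-fine multimodal registration (adaptive SURF keypoint
    thresholding driven by structural similarity, followed by Demons
    nonrigid refinement), per-pixel 3D light-field feature extraction from
    organized depth data (distances and angles relative to the light
    source and camera via local SVD plane fitting), and reflectance
    correction against matte hemisphere references using a shallow neural
    network or nearest-neighbour search over a reference spectra database.
    A synthetic Lambertian scene renderer with known ground truth stands
    in for the physical imaging rig, so the whole pipeline can be
    exercised and validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    yaml,
    jsonlite,
    nnet,
    rpart,
    randomForest,
    e1071,
    kernlab,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
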