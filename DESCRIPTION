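Package: plantalign
Title: Multimodal Registration of Fluorescence and Visible-Light Plant Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated registration of multimodal plant images from
    high-throughput phenotyping platforms, aligning fluorescence (FLU) images
    to visible-light (VIS) images so that high-contrast FLU segmentation masks
    can be transferred to optically heterogeneous VIS images. Provides three
    independent similarity-transform registration engines (robust feature-point
    matching, Fourier-Mellin phase correlation, and Mattes-style mutual
    information maximization), a preprocessing chain (grayscale and color-edge
    representations, resolution prescaling, anti-aliased downscaling,
    background-mat removal), transform admissibility gating, success-rate and
    overlap-ratio evaluation, a scale-sweep combiner over methods and image
    representations, and an integrated-mask fusion of multiple registrations
    that piecewise-approximates nonuniform leaf motion. Includes a seeded
    synthetic phantom generator with known ground-truth transforms for
    benchmarking every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
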