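Package: lamwave
Title: Waviness Quantification of Elastic Lamellae in Tomographic Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the waviness of elastic-lamella cross-sections in
    grayscale tomographic image stacks via the arc-chord ratio r_ec, the
    ratio between the end-to-end (Euclidean-like) distance and the
    curvilinear (geodesic-like) length of each lamella fragment. Provides
    Otsu-based thresholding with area, bounding-box-occupancy and solidity
    filters for fragment extraction; skeletonization with longest-path
    reduction and a subsample/oversample scheme for subpixel length
    estimation; per-stack aggregation with a nonparametric two-cohort
    comparison (Wilcoxon rank-sum with continuity correction); and a
    seeded synthetic-stack generator with analytically known curve lengths
    for validation of the full pipeline.
License: MIT
Encoding: UTF-8
Imports:
    grDevices,
    igraph,
    jsonlite,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
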