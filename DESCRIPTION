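Package: fmmseg
Title: Region-Based Fast Marching Segmentation of Lung Nodules in CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Segments pulmonary nodules in thoracic CT slices with a
    multi-label fast marching method. A gradient-derived speed image and a
    gradient-filtered seed grid drive simultaneous front propagation from
    many seeds, partitioning the nodule crop into small regions; regions
    are grouped with deterministic k-means and merged into a final binary
    mask by a mean-intensity criterion. Includes CT preprocessing
    (resampling, lung segmentation with per-lung convex hulls,
    Hounsfield-unit normalization, nodule-centered cropping), a synthetic
    phantom-nodule generator covering solid, sub-solid, cavitary,
    juxtapleural and juxtavascular cases with known ground truth, and
    objective evaluation via the Dice coefficient and long/short-axis
    diameter errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
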