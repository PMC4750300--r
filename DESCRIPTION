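Package: ciliometry
Title: Primary Cilium Length Measurement from Confocal Z-Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures primary cilium length from calibrated confocal Z-stacks
    by three complementary methods: maximum intensity projection (MIP),
    the Pythagorean estimate combining projected length with axial slice
    extent (PyT), and direct measurement on an obliquely resliced vertical
    plane built by bilinear interpolation (DAAS). Includes a flat/angled
    cilium classifier based on slice span, a synthetic Z-stack renderer
    producing cilia of known 3D geometry under an anisotropic Gaussian
    point-spread function for validation, and the method-agreement
    statistics used to compare the methods: two-way absolute-agreement
    intraclass correlation with Landis-Koch interpretation, Bland-Altman
    limits of agreement, and independent-samples t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
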