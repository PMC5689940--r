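Package: fffqa
Title: Analytical Source Modelling and Independent Planar Dose Calculation
    for FF and FFF IMRT QA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Implements a common analytical head-scatter source model for
    flattened (FF) and flattening-filter-free (FFF) photon beams and an
    independent planar dose calculation algorithm for IMRT quality
    assurance.  The extra-focal source is a sum of bivariate Gaussians on a
    plane below the target; in-air output factors are computed by
    back-projecting collimator edges onto the source plane and integrating
    with error functions; planar fluence of step-and-shoot segments is
    built from a per-ray MLC transmission model (rounded leaf ends,
    interleaf and tongue-and-groove strips) plus the extra-focal integral,
    modulated by a fourth-degree off-axis-ratio polynomial for FFF beams,
    and convolved with a triple-Gaussian dose deposition kernel.  Includes
    staged commissioning by bounded least squares with detector
    volume-averaging correction, 2D gamma comparison with local or global
    dose-difference criteria, synthetic fixture generators, and plain-text
    readers and writers for all model and plane formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
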