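Package: phantomqa
Title: Automated Quality Assurance Metrics for MRI Phantom Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Vendor-independent post-processing for magnetic-resonance
    quality assurance on a homogeneous cylindrical phantom. Detects the
    phantom automatically and places all regions of interest, computes
    structural image-quality metrics (percent signal ghosting, percent
    image uniformity, and two NEMA signal-to-noise estimators from
    spin-echo repetitions), temporal stability metrics from an
    echo-planar time series (signal-to-fluctuation-noise ratio, percent
    fluctuation, drift, Weisskoff analysis and the radius of
    decorrelation), and cross-session repeatability summaries with
    control limits. Includes a synthetic phantom simulator with known
    ground truth so every metric can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
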