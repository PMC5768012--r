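Package: track4d
Title: 4D Treatment Planning with Tumor Tracking and Dose Accumulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale four-dimensional radiotherapy treatment planning for
    respiratory-moving targets. Generates seeded synthetic 4D phantoms
    (8 amplitude-binned breathing phases with tumor, organ-at-risk and body
    structures, density grids and ground-truth deformation fields), converts
    breathing traces into 8-phase probability density functions, builds
    beam's-eye-view MLC apertures with virtual-couch-shift tumor tracking or
    a fixed internal-target-volume (ITV) aperture, computes dose with a
    deterministic attenuation + penumbra engine, accumulates phase doses on
    the reference (maximum-inhale) phase, and evaluates dose-volume
    histograms, TG-101 organ-at-risk metrics, relative organ motion and
    sparing-versus-motion regressions comparing tracked against ITV plans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
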