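Package: octLBP
Title: Local Binary Pattern Texture Classification of 3D OCT Volumes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for automated detection of age-related macular
    degeneration (AMD) from 3D optical coherence tomography (OCT)
    volumes using local binary pattern (LBP) texture features and a
    linear support vector machine. Implements the four classic LBP
    variant mappings (classic, rotation-invariant, uniform, and
    rotation-invariant uniform) as 256-entry lookup tables, per-slice
    histogram statistics with optional saturating counters, three
    volume-level feature aggregation schemes (slice-chain,
    slice-threshold, slice-sum), linear SVM inference from explicit
    dual-solution weight and bias formulas with a sequential
    multiply-accumulate emulation of the hardware datapath, a
    bit-accurate fixed-point inference simulator with word-length
    sweeps, and a synthetic two-class OCT-like volume generator so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
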