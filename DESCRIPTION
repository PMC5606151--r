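Package: rpeakr
Title: Adaptive R-Peak Detection in Single-Channel ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects R-peaks in single-channel electrocardiograms using
    eight-level wavelet multiresolution enhancement (bior6.8 filter bank with
    dyadic band selection and soft shrinkage), mirroring of large negative
    deflections so that inverted (PVC-like) QRS complexes become positive,
    sign-of-difference local-maximum location, and adaptive per-segment
    amplitude and time-interval thresholding with width/amplitude arbitration
    of closely spaced candidates. Includes beat-level evaluation (sensitivity,
    positive predictivity, accuracy) against reference annotations within a
    configurable tolerance window, a threshold-coefficient sweep, WFDB and CSV
    input/output, a synthetic ECG generator with exact ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse,
    jsonlite
Config/testthat/edition: 3
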