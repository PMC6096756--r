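Package: centralgain
Title: Central-Gain Analysis of Noise-Induced Hearing Loss Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Quantitative analysis chain for noise-exposure auditory
    experiments in rodents: auditory brainstem response (ABR) preprocessing,
    peak 1-4 measurement, two-standard-deviation threshold determination and
    central-gain amplitude ratios; conditioned lick-suppression psychophysics
    with signal-detection-theory d-prime thresholds; acoustic startle
    quantification; serial-section immunolabel densitometry with section
    leveling and histogram auto-thresholding (triangle and Renyi entropy);
    3D reconstruction, affine template registration and tonotopic
    (quarter-octave) density profiles; and optical-fractionator stereology.
    Every input modality has a synthetic generator with known ground truth,
    so the full pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
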