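Package: csfdyn
Title: Real-Time Phase-Contrast MRI Analysis of Cerebrospinal Fluid Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing of real-time phase-contrast (RT-PC) MRI velocity
    maps for cerebrospinal fluid (CSF) flow quantification: pulsatility-based
    region-of-interest segmentation, stationary-tissue background (eddy
    current) correction, velocity de-aliasing, and flow integration; beat-to-
    beat cardiac cycle segmentation at flow minima with 32-point cycle
    reconstruction and extraction of net flow, amplitude, stroke volume,
    cardiac period and peak mean velocities; a time-domain, phase-shift-aware
    quantification of free-breathing effects on these parameters
    (inspiration-minus-expiration differences swept over a breathing phase
    shift); Bland-Altman percentage agreement utilities; and a synthetic-data
    generator producing CSF-like flow records with known injected cardiac and
    respiratory modulation for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
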