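Package: silentsub
Title: Silent Substitution Stimulus Design for Multiprimary Stimulators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes photoreceptor-directed (silent substitution) stimuli
    for visual stimulators with three to five spectrally distinct primary
    lights. Given calibrated primary emission spectra and mean luminances,
    it builds the photoreceptor excitation (A-) matrix for a standard
    observer with L-, M-, S-cone, rod and melanopsin fundamentals, inverts
    its contrast-normalized form to obtain the per-primary Michelson
    contrasts that realize a requested photoreceptor contrast vector,
    checks technical feasibility against device luminance ranges, and
    validates residual contrasts under individually modified fundamentals
    (macular pigment density, lens age, L/M lambda-max shifts). Includes
    spectral utilities (resampling, radiance normalization, luminance,
    CIE 1964 chromaticity), import/export of spectra and solutions, and
    fully synthetic fixtures so that all computations run offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    readxl,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
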