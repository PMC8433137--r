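Package: regfreenav
Title: Registration-Free Surgical Navigation: Transform Chains,
    Registration Baselines, and Target Registration Error Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for registration-free intra-operative navigation in
    craniofacial surgery. Provides frame-aware rigid and affine transform
    algebra with DICOM patient-coordinate conventions (RAS/LPS, Image
    Position Patient), closed-form point-based fiducial registration and
    iterative-closest-point surface registration, the splint-borne
    dynamic-reference-frame transform chain that substitutes a
    pre-operatively known pose for intra-operative registration, a
    Monte-Carlo simulator of a cadaver accuracy study (factorial design
    over tracking techniques, registration methods, observers, repetitions
    and targets), first-order target registration error theory, and a
    square-root-TRE linear mixed-model accuracy analysis with derived
    per-group intercept and slope lines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lme4
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
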