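Package: sleeptopo
Title: Topographic Heritability Analysis of the Sleep EEG in Twin Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate the genetic and shared-environmental contribution
    to the scalp topography of sleep EEG spectral power in twin designs. The
    pipeline takes multichannel sleep recordings with hypnograms, computes
    per-epoch power density spectra (averaged 5-s Hanning windows at 0.2-Hz
    resolution), rejects artifactual epochs and channels by spectral-power
    thresholds, normalizes power per frequency bin across derivations,
    aggregates canonical frequency bands into per-state topographic maps, and
    compares maps across monozygotic, dizygotic, unrelated and within-subject
    retest pairs via Fisher-z averaged Pearson correlations. Heritability and
    shared-environment fractions are estimated with Falconer's formula. A
    synthetic twin-cohort generator with a known ACE variance structure, at
    the topography and the raw-signal level, makes every stage testable
    without access to real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
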