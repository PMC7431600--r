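Package: condvaso
Title: Conducted Vasoconstriction Analysis by Exponential Decay Fitting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing conducted vasomotor responses in
    microvessels. Reduces per-vessel diameter time series (baseline,
    stimulation, recovery phases sampled along the vessel) to
    distance-resolved relative-constriction profiles, applies inclusion
    and zero-truncation rules, pools vessels by group, fits the spatial
    decay model y = a*exp(b*x) by nonlinear least squares, derives the
    length constant -1/b, and compares decay rates between groups with a
    percentile bootstrap. Includes a seeded synthetic-cohort generator
    emulating afferent-arteriolar recordings so the whole pipeline is
    testable without raw microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
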