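Package: psrmorph
Title: Automated Morphometry of Collagen and Fat in Picrosirius Red Stained Myocardium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies collagen, fat, and myocyte proportions in Picrosirius
    Red (PSR) stained ventricular myocardium from calibrated RGB section
    images. Pixels are classified by configurable colour-band thresholds,
    fat vacuoles are recovered by morphological analysis of enclosed
    unstained regions, vessel lumens are detected by an elliptical shape
    score and their perivascular collagen cuffs excluded from analyzable
    tissue, and free-wall sections are partitioned into equal-area
    epicardial and endocardial halves. Composition percentages are analysed
    on the log scale with a multilevel model (random intercept per heart),
    reported as geometric means with 95% confidence intervals and
    between-location ratio contrasts. A synthetic-slide and clustered-study
    generator with known ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    lme4,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
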