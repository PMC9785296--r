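Package: pronomorph
Title: Linear and Outline-Based Morphometry of the Cimicid Pronotum
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to compare linear and outline-based morphometric
    characterization of the pronotum in bed bugs, bat bugs and swallow bugs
    (Hemiptera: Cimicidae). Implements elliptic Fourier analysis of closed
    pseudolandmark contours with size extraction via the semi-major axis of
    the first harmonic ellipse and normalized (NEF) shape coefficients;
    Darroch-Mosimann log-size and log-shape ratios from three linear
    pronotum measurements; permutation ANOVA on size; leave-one-out
    validated classification by Gaussian maximum likelihood (size) and a
    small multilayer perceptron (shape); UPGMA clustering with
    cluster-to-species concordance; and allometry quantification by
    regressing shape variables on size. A synthetic pronotum generator with
    controllable species/sex structure makes the whole pipeline testable
    without specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape
Suggests:
    nnet,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
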