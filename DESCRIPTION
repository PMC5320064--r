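Package: coagferm
Title: Model-Based Evaluation of Bacillus coagulans Cofermentation Under Lignin Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for thermophilic Bacillus coagulans cofermentation
    of lignocellulose-derived sugars (glucose, xylose, arabinose) to L-lactic acid
    in lignin-supplemented media. Provides an unstructured Monod-kinetics ODE model
    of triple-sugar cofermentation with catabolite repression, lignin and product
    inhibition, and Luedeking-Piret lactate formation; a real-coded genetic
    algorithm for nonlinear least-squares parameter estimation; fit-quality
    statistics (residual sigma, R-squared, single-factor ANOVA at 95 percent
    confidence); high-throughput microplate optical-density screening with logistic
    growth-curve fits (A, mu_max, lambda), beta extraction and beta-versus-lignin
    regression with tolerance extrapolation; fermentation performance metrics
    (volumetric productivity, yield coefficients, total-cell-count regression);
    UV-spectrum decolorization analysis for alkali-lignin, ferulic acid and
    vanillin uptake; and synthetic-data generators with known ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
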