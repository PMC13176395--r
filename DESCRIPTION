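Package: respigate
Title: Respiratory Gating Simulation and Image-Quality Analysis for PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates respiratory breathing traces and list-mode-style PET
    coincidence event streams, applies two data-driven respiratory gating
    methods (fixed-offset quiescent-period gating and cycle-specific
    amplitude-driven gating), and quantifies breathing regularity via the
    cycle-duration dispersion (tvar), the gating overlap fraction, and a
    spectral R value. Includes a motion-blurred NEMA-style image-quality
    phantom simulator with Poisson count noise, scoring of contrast recovery,
    background variability, contrast-to-noise ratio and liver
    signal-to-noise, and a multi-arm comparison harness using Kruskal-Wallis,
    Wilcoxon signed-rank and paired t tests with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
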