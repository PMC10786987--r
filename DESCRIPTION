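Package: nmdartools
Title: Kinetic, Dose-Response, Imaging and Group-Statistics Analysis of
    NMDA-Receptor Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of NMDA-receptor (NMDAR) whole-cell
    electrophysiology and fluorescence imaging, with an emphasis on
    C-terminal-domain truncation variants of GluN2 subunits. Provides a
    four-state gating model (desensitized, closed, open, MK-801-blocked)
    with deterministic propagation under arbitrary solution-application
    protocols; macroscopic open-probability estimation from the onset of
    MK-801 open-channel block by constrained kinetic fitting;
    single-exponential desensitization analysis; Hill-equation
    dose-response fitting; neurosteroid modulation indices;
    surface-to-intracellular expression ratios, PSD-95 colocalization and
    puncta counting from fluorescence images; a group-statistics stage
    (power transformation, studentized-residual outlier screening, ANOVA
    with Dunnett and Duncan post-hoc comparisons, paired t tests); and
    seeded synthetic-data generators with ground-truth sidecars for every
    analysis substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    minpack.lm,
    MASS,
    car,
    multcomp,
    mvtnorm,
    igraph,
    yaml,
    tiff,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
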