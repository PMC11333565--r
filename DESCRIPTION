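Package: nanonorm
Title: Quality Control and Reference-Gene-Driven Normalization of
    NanoString nCounter Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parses NanoString nCounter Reporter Code Count (RCC) lane
    files into an annotated count matrix, runs lane-level quality control
    (field of view, binding density, positive-control linearity, scaling
    factor, counts below background), estimates and corrects background
    from negative controls or alternative low-expressed endogenous genes,
    and normalizes counts by positive-control scaling, per-lane ladder
    regression, or reference-gene content scaling.  Reference genes are
    screened from the endogenous panel by coefficient of variation, ranked
    with a geNORM-style stability algorithm (optionally weighted), and
    refined by group-driven differential-expression filtering
    (Kruskal-Wallis, pairwise Wilcoxon, reverse sequential feature
    selection).  An RUVg-style factor model on control genes removes
    unwanted variation, with optional median-of-ratios pre-normalization
    and a k-selection scan.  Normalization quality is evaluated through
    relative log expression, per-lane interquartile ranges and principal
    component diagnostics.  A synthetic RCC generator with known ground
    truth and a file-based pipeline with provenance logging support fully
    reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
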