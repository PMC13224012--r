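Package: mitoscreen
Title: High-Content Profiling of Mitochondrial Redox State from
    Multichannel Fluorescence Images
Version: 0.1.0
Authors@R: person("Imaging", "Pipelines", role = c("aut", "cre"),
    email = "imaging.pipelines@example.org")
Description: An end-to-end high-content screening pipeline for live-cell
    mitochondrial physiology: synthetic multichannel fluorescence plate
    simulation with exported ground truth, nuclei/cell/mitochondria
    segmentation, background-corrected single-cell intensity
    quantification of membrane potential (MMP), total ROS and
    mitochondrial ROS, a 541-feature morphological profiling catalogue
    (shape, intensity, Haralick texture, cross-channel correlation,
    granularity, radial distribution, neighbours, location), PCA and
    hierarchical-clustering phenotyping of per-image profiles, and
    redox-coupling statistics comparing Pearson correlations between
    MMP and (mt)ROS with Fisher z tests. Includes group-comparison
    statistics (Student's t, one-way ANOVA) and a delta-delta-Ct qPCR
    relative-quantification calculator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml,
    tiff,
    ape,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
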