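Package: cristamorph
Title: Morphometrics of ATP Synthase Dimer Rows and Mitochondrial Cristae
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the geometry of ATP synthase dimers
    shapes mitochondrial crista membranes. Generates synthetic lamellar
    crista meshes decorated with rows of dimer poses with known ground
    truth, measures the quantities used to characterise dimer architecture
    (dimer-head angle, membrane curvature angle, central-stalk separation,
    inter-dimer spacing, yaw offset) and crista morphology (surface area,
    enclosed volume, surface-area-to-volume ratio, crista width), and
    compares populations between species presets with Welch's t-test and
    the Mann-Whitney U-test. Includes readers and writers for PLY/OBJ
    meshes, MRC label volumes, and TSV/STAR pose tables, and an
    end-to-end reproduction pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
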