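Package: cephalomorph
Title: 3D Cephalometric Shape Analysis and Normative Skull Templates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based 3D cephalometry for craniofacial shape analysis.
    Superimposes 18-landmark skull configurations by generalized Procrustes
    analysis, derives dimensionless facial proportions from inter-landmark
    distances, screens them for normality and compares them between groups
    with Benjamini-Hochberg-corrected t-tests, partitions each sex into
    sub-phenotypes (dolichofacial vs brachyfacial) by k-means clustering,
    and morphs annotated template skull meshes onto group mean shapes with a
    3D thin-plate spline. Includes a calibratable synthetic-cohort generator
    that realizes landmark configurations with prescribed proportions, plus
    PLY/STL mesh input/output and a command-line entry point.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    nortest,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
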