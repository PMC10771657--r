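Package: dlmfem
Title: Finite-Element Analysis of Residual Discoid Lateral Meniscus Volume
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale finite-element pipeline for studying how the residual
    volume of a discoid lateral meniscus after partial meniscectomy changes
    tibiofemoral shear (Tresca) and compressive (minimum principal) stresses.
    Provides a parametric synthetic knee geometry (rigid femur and tibia,
    cartilage layers, a C-shaped medial meniscus and a discoid lateral
    meniscus), volume-ratio partitioning and virtual resection of the discoid
    meniscus into a 15-model residual family, Table-driven constitutive models
    (isotropic elasticity, transversely isotropic meniscus, Neo-Hookean
    ligament fibers), a small-strain tetrahedral contact solver under a 1150 N
    static stance load, and stress postprocessing with per-compartment peak
    extraction and percent-change reporting.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
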