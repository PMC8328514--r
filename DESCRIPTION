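Package: receptorOligo
Title: Quantification of GPCR Oligomerization from Chromatography,
    Densitometry and Dimer-Interface Geometry
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify homo-oligomerization of membrane receptors,
    built around the adenosine A2A receptor and its intrinsically disordered
    C-terminus. Deconvolves size-exclusion chromatography traces into
    high-molecular-weight oligomer, dimer and monomer species by
    multi-Gaussian fitting and reports monomer-equivalent oligomer levels
    with delta-method confidence intervals; quantifies western-blot lane
    densitometry; analyses dimer configurations geometrically (electrostatic,
    hydrogen-bond and non-polar cross-protomer contacts, interface symmetry,
    helical tilt, interacting-helix screening, Daura RMSD clustering);
    and provides solution-biophysics calculators (ionic strength,
    Debye screening length, Kyte-Doolittle hydropathy, melt-curve
    derivative analysis, turbidity-based aggregation classification).
    Seeded synthetic-data generators with ground-truth manifests make every
    stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    signal,
    bio3d,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
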