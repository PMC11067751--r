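Package: metalloscan
Title: Symmetry-Aware Analysis of Metal Binding Sites in Protein Crystal
    Structure Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing covalent metal binding in protein crystal
    structures collected as a time series. Parses PDB-format models with
    their unit cell and space group, expands crystallographic symmetry to
    find crystal contacts, builds metal coordination spheres with
    distance standard uncertainties propagated from the Cruickshank
    diffraction precision index, classifies metal-donor distances as
    covalent or weak against covalent-radius sums and small-molecule
    survey references, characterises aromatic ring stacking (centroid
    distances, interplanar angles, face-to-face/edge-to-face criteria)
    across symmetry mates, and tracks site occupancies and anomalous peak
    heights over time grouped by X-ray wavelength. Includes a synthetic
    ground-truth fixture generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
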