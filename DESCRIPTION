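Package: ChemHarvest
Title: Harvest 3D Molecular Structures from PDF and Text Supplementary Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts Cartesian atomic-coordinate blocks buried in the
    supplementary-information documents of computational-chemistry articles
    (PDF or plain text), reconstructs covalent connectivity with a
    covalent-radii distance rule, and writes ready-to-compute molecule files
    (SDF/MOL V2000, XYZ, Gaussian job files) together with bond-matrix and
    residual-text reports. Includes a deterministic generator of synthetic
    supplementary-style documents with ground-truth manifests for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, jsonlite, stats, utils, tools
Suggests: testthat (>= 3.0.0), ChemmineR, ChemmineOB, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
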