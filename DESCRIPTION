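Package: dnareadout
Title: Protein-DNA Interface Geometry, Groove Shape and Operator Threading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Analysis of protein-DNA recognition in atomic structures of
    transcription factor-operator complexes: nucleic-acid backbone torsions
    and B_I/B_II substate classification, base-pair and step parameters
    (propeller twist, roll, base-pair origins), minor- and major-groove
    width profiles from cross-strand phosphate distances, distance-based
    protein-DNA contact classification (hydrogen bonds, salt bridges, van
    der Waals), Shrake-Rupley solvent-accessible and buried surface areas,
    and in-silico operator threading with steric collision scanning.
    Includes a fiber-model B-DNA generator so every analysis stage can be
    exercised on synthetic duplexes of arbitrary sequence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
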