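Package: sslock
Title: Structure-Guided Disulfide Locking of Two-State Protein Complexes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for designing engineered disulfide bonds that lock a
    two-state protein complex (such as the integrin alphaIIb-beta3
    headpiece) in a chosen conformation. Screens residue pairs across two
    coordinate sets for C-beta/C-beta distances that are bondable in one
    state and widely separated in the other, predicts the monoisotopic
    masses and m/z values of diagnostic disulfide-crosslinked peptides
    after in-silico proteolysis (trypsin, Asp-N, sequential digests) for
    mass-spectrometric verification, and implements the companion assay
    quantifications: net normalized fluorescence intensity (NNFI) from
    flow-cytometry geometric means, percent inhibition of adhesion, and
    the elliptical form factor of cell masks. Includes generators for
    synthetic two-state structures, mutant sequence pairs, fluorescence
    events and ellipse masks so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
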