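Package: rsfit
Title: Real-Space Model Fitting, Refinement and Validation for Cryo-EM Maps
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Headless model-building toolkit for fitting macromolecular
    models into cryo-EM density maps: Fourier-space map blurring and
    sharpening with optional finer-grid resampling, stochastic rigid-body
    ("jiggle") fitting, robust Geman-McClure self-restrained real-space
    refinement of whole chains, backrub rotamer side-chain fitting,
    torsion ("JED") flips, register nudging, fragment surgery, blob
    navigation, and a validation suite (Ramachandran and Kleywegt
    analysis, rotamer probabilities, B-factor statistics, per-residue
    density fit, dictionary-based ligand distortion). Ships deterministic
    synthetic-fixture generators (ideal-geometry polypeptides, Gaussian
    atom maps) so every algorithm is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    Biostrings
Config/testthat/edition: 3
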