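Package: angtraj
Title: Trajectory Marker Analysis and Variant-Effect Classification for Angiogenin
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts four structural and dynamic markers from molecular-dynamics-style
    trajectories of human angiogenin (backbone RMSD, His114 rotamer switching,
    hydrogen-bond interaction paths from a mutation site to His114 mediated through
    Leu115, and solvent accessibility/compaction of the nuclear localization signal
    arginines R31-R33) and combines them into a rule-based deleterious/benign verdict
    with per-mechanism loss-of-function flags. Includes PDB structure and multi-model
    trajectory input/output, in-silico point mutation with ideal side-chain templates,
    a Shrake-Rupley solvent-accessible surface area implementation, Kabsch
    superposition, and a synthetic-trajectory generator that injects each marker
    independently at known strength for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
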