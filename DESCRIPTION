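Package: specbind
Title: Spectroscopic Analysis of Drug-Protein Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing protein-ligand binding by steady-state
    fluorescence spectroscopy. Implements Stern-Volmer, modified
    Stern-Volmer (accessible-fraction) and double-logarithmic
    (binding-sites) quenching fits with optional two-regime handling,
    quenching-mechanism classification against the diffusion-collision
    limit, red-edge excitation shift (REES) and synchronous-fluorescence
    conformation metrics, resonance light scattering (RLS)
    aggregation-onset detection by hinge regression, Forster resonance
    energy transfer (overlap integral, Forster radius, transfer
    efficiency, donor-acceptor distance), inner-filter and dilution
    corrections, and a seeded synthetic-spectra generator for validating
    every fit by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
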