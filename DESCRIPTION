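Package: smSERS
Title: Single-Molecule SERS Event Detection and Protein Structure Markers
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-molecule surface-enhanced Raman
    spectroscopy (SERS) at optically trapped plasmonic nanocavities. Provides
    a synthetic spectrum generator with the statistical structure of bi-analyte
    (BiASERS) and protein measurement campaigns, Savitzky-Golay preprocessing
    and second-derivative analysis, the three-sigma rare-event detection rule
    with single/dual analyte classification, amide-I secondary-structure and
    tyrosine Fermi-doublet markers for amylin (hIAPP) species assignment, and
    the small physical-chemistry calculations that accompany such experiments:
    Henderson-Hasselbalch protonation and net charge, strong acid-base mixing,
    vibrational frequency scaling, and Rayleigh-regime optical gradient forces
    and trapping potentials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
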