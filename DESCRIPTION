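Package: solvshift
Title: Solvent-Effect Analysis of Computed NMR Chemical Shifts for Conformer Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding which conformer of a flexible molecule is present in
    solution by confronting quantum-chemically computed NMR chemical shifts and
    solvation energies with experiment. Converts GIAO isotropic shieldings to
    TMS-referenced shifts, averages equivalent nuclei, computes the mean-centered
    RMSD agreement statistic with precision-window discrimination verdicts,
    tabulates relative energies across implicit/explicit solvation model variants
    (including fragment solute-only bookkeeping and input-sensitivity deltas),
    Boltzmann- or equally-weighted ensemble averaging, hydrogen-bond and torsion
    geometry analytics on XYZ structures, a seeded microsolvation cluster builder,
    and a synthetic-data generator for benchmarking shift-based versus energy-based
    conformer recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
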