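Package: diawin
Title: Design and Evaluation of dia-PASEF Isolation-Window Schemes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Places variable-width two-dimensional quadrupole isolation
    windows for dia-PASEF acquisition on trapped ion mobility - quadrupole
    time-of-flight instruments. Given a spectral library of peptide
    precursors (m/z, reduced ion mobility 1/K0, charge), the package bins
    precursors at equal density along m/z, models the scanned region of
    the m/z-ion mobility plane as a trapezoid, optimizes the trapezoid
    corners by Gaussian-process (Bayesian) optimization to maximize
    precursor coverage, and exports instrument-ready window tables
    together with coverage diagnostics. Includes a synthetic precursor
    cloud generator (proteome and phospho-enriched modes) so that all
    functionality can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
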