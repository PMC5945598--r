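Package: actifil
Title: Rigid-Body, Helical and Interface Analysis of Actin Filament Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy tools for analysing conformational transitions in actin and
    actin-binding-protein filament models. Provides atomic-model input/output
    (PDB and mmCIF) as atom-level tibbles, least-squares (Kabsch) superposition
    and screw-axis decomposition between rigid domains, a two-pass per-residue
    standard-deviation search for rigid bodies across conformer ensembles,
    helical filament construction and symmetry fitting (genetic twist, rise,
    strand rotation), rigid-body grafting of a bound protein (such as cofilin)
    onto a filament including hybrid two-strand models, and van der Waals
    interface and steric-collision analysis. A seed-deterministic synthetic
    structure generator with planted ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
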