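Package: panrep
Title: Antibody Repertoire Profiling for Phage-Display Hapten Selections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterization of sheep scFv antibody repertoires sampled before
    and after phage-display panning against hapten antigens. Provides Kabat
    numbering of heavy and lambda variable domains by profile alignment,
    framework/CDR region annotation and CDR length profiling, strict Chothia
    SDR-template canonical structure classification (including a class "X"
    label for loop lengths without a known canonical class), per-position
    amino-acid variability with a seven-group biophysical classification,
    conserved-site comparison of pre- versus post-selection repertoires,
    frequency tables with chi-square goodness-of-fit tests for canonical class
    dominance, and a seeded synthetic repertoire generator with ground-truth
    records for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
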