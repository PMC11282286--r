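Package: fiberdemix
Title: Demixing of Single-Source Activity from Short Multimode-Fiber Photometry Videos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recovering single-source fluorescence time traces from
    videos of scattering fingerprint patterns transmitted by short multimode
    fibers. Provides a synthetic-data generator (guided LP-mode forward model
    for a scaled step-index fiber, a phenomenological spiral-ring fingerprint
    model, calcium-transient and neuropil trace generators, a scattering-layer
    model, and camera digitization), an unconstrained non-negative matrix
    factorization demixer (NNDSVD initialization, coordinate-descent and
    multiplicative-update solvers, rank scanning for source counting), and
    evaluation machinery (ground-truth correlation tables, greedy descending
    assignment, diagonal and cross-talk summaries), plus TIFF/CSV/JSON input
    and output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    tiff,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
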