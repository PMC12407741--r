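Package: gspfinger
Title: Comparative Graph Signal Processing Features for Connectome Fingerprinting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a comparative benchmark of graph-signal-processing (GSP)
    features derived from structural connectomes and regional fMRI time courses.
    Implements four graph shift operators (unnormalized, normalized and
    random-walk Laplacians, and the modularity matrix) and their connectome
    harmonics; five structure-function coupling feature types (power spectral
    density, energy, alignment, liberality and the structural decoupling index)
    across a full grid of pipeline parameters; six quality criteria spanning
    robustness to acquisition settings and head motion, test-retest reliability
    (ICC(A,1)), subject fingerprinting via Hungarian one-to-one assignment, and
    generalizability to parcellation changes, combined into a consensus ranking;
    a spectral embedding of feature-pattern similarity; and a synthetic
    multi-subject cohort generator (subject-specific connectomes, graph-smooth
    BOLD-like signals, session effects and a motion confound) so the whole
    pipeline runs end-to-end without restricted data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
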