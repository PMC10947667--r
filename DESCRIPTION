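Package: ghostshift
Title: Ghost Lineages and the Relative Timing of Horizontal Gene Transfers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for studying how ghost lineages (extinct or
    unsampled taxa) distort branch-length-based inference of the relative
    timing of horizontal gene transfers. Simulates complete birth-death
    species trees with extinct lineages retained, grafts transferred gene
    histories onto donor branches, applies extinction pruning and incomplete
    taxon sampling, and measures how often the inferred order of two
    transfers into a shared recipient stem is reversed ("shifted") as a
    function of the extinction fraction and the sampling fraction. Also
    provides normalized terminal-branch-length and lineages-through-time
    diagnostics, and the analytic conditions under which a timing shift is
    observable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
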