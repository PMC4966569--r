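Package: niebtools
Title: Nucleosome-Inhibiting Energy Barriers: Spacing, Occupancy and
    Selection Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for nucleosome-inhibiting energy barriers
    (NIEBs) in a genome: inter-barrier spacing statistics and
    nucleosome-class assignment, border-aligned profiles of nucleosome
    occupancy and GC content, per-barrier depletion testing by Z-score,
    position-resolved interspecies and intraspecies divergence rates with
    CpG masking, equilibrium GC content from substitution rate matrices,
    and a background-corrected selection ratio with a bootstrap neutral
    null.  Includes a synthetic-data generator emulating Poisson-placed
    AT-rich barriers with poly(dA:dT) edges, statistically positioned
    nucleosome dyads, neutral and selected substitution processes with
    CpG hypermutability, and patchy mappability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
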