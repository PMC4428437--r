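Package: entropull
Title: Entropic Pulling by Hsp70 and Chaperone-Assisted Protein Import
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage pipeline for quantifying chaperone-assisted protein
    translocation. Stage one samples a coarse-grained (one bead per residue)
    model of a membrane-tethered substrate bound to a two-domain Hsp70
    chaperone and estimates the entropic-pulling free-energy profile from the
    fraction of wall-compatible configurations. Stage two assembles a
    one-dimensional import landscape (sigmoidal unfolding term plus the
    nearest-bound-chaperone pulling term) and measures first-passage import
    times by Metropolis Monte Carlo, including ensemble averages over random
    binding-site distributions, acceleration ratios and exponential
    extrapolation of unassisted times.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
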