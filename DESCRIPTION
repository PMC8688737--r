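Package: hardwater
Title: Monte Carlo Simulation of Short-Range Hard-Core Water-Like Fluids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: NVT Metropolis Monte Carlo simulation of two simple water-like
    model fluids with hard cores and optional dipole-dipole interactions: a
    primitive model of water descended from the TIP4P geometry (hard sphere
    with off-center square-well association sites) and the fluid of dipolar
    hard regular tetrahedra.  Dipoles can be switched off, screened at short
    range by a cubic smoothstep, or applied over the full range, with
    reaction-field electrostatics beyond a spherical cutoff.  The analysis
    layer produces site-site pair correlation functions, first-shell
    coordination numbers and block-averaged reduced energy decompositions.
    The Monte Carlo kernels (separating-axis tetrahedron overlap tests, pair
    energies, trial moves) are implemented in C++ via Rcpp.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
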