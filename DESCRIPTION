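Package: oxyuq
Title: Variance-Based Uncertainty Mapping for Ocean Oxygen Projections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gridpoint-wise variance-based global sensitivity analysis for
    perturbed-parameter ensembles of marine biogeochemical models. Builds a
    Gauss-Hermite collocation design over three uncertain parameters (detritus
    sinking speed, vertical background diffusivity, maximum phytoplankton
    growth rate), fits per-gridpoint Polynomial Chaos Expansions in Hermite
    polynomials, decomposes output variance into Sobol main effects and
    interactions, and derives the spatial diagnostics used to map projection
    uncertainty of water-column oxygen minima: noise-to-signal ratios,
    ensemble spread, coefficient of variation, low-variance masking, regional
    aggregation and benchmarking-region scores. Includes a synthetic
    multi-column diffusion-remineralization ocean model that emulates the
    ensemble-archive structure (125 runs, three time slices) so the full
    pipeline can be exercised end-to-end without an Earth-system model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ncdf4,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
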