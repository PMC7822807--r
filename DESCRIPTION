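Package: mitralsim
Title: Position-Based Simulation of the Mitral Valve Apparatus with Editable Chordae Tendineae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates opening and closing of the mitral valve with an extended
    position-based dynamics (XPBD) cloth model: distance, dihedral bending,
    area-conservation and vertex-triangle collision constraints driven by
    simplified pressure and velocity force fields. The chordae tendineae are
    completed by a heuristic model with one-sided distance constraints anchored
    at two papillary muscle tips, including heuristic tip placement and
    rest-length initialization from the annulus plane. Cord rest lengths can be
    edited at three granularities while the simulation runs, and closed-valve
    results are scored against tracing polylines (minimum, median, maximum and
    mean deviation) together with a prolapse detector. A deterministic
    parametric generator provides competent and pathological synthetic valves
    for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
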