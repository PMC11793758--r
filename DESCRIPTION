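Package: ocamorph
Title: Three-Dimensional Morphometry of Occlusal Appliance Deformation
Version: 0.1.0
Authors@R: person("ocamorph", "developers", role = c("aut", "cre"),
    email = "ocamorph@example.org")
Description: Quantifies storage-induced deformation of PMMA occlusal
    appliances from pairs of 3D surface scans. Provides STL mesh input and
    output, best-fit rigid alignment by iterative closest point matching,
    signed surface deviation fields with a scanner-error cutoff, deformed
    area and volume outcomes, cross-sectional deviation profiles, a
    sphere-fitting scanner accuracy protocol that derives the cutoff, exact
    paired Wilcoxon signed-rank comparison of wet versus dry storage, and a
    synthetic specimen generator with known parametric deformation fields
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
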