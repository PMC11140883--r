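Package: auriplan
Title: Mirror-Symmetry Planning, Marker-Based Guidance and Outcome
    Evaluation for Ear Reconstruction Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometry toolkit for auricular (ear) reconstruction workflows
    based on 3D surface scans. Estimates the midsagittal plane of a head mesh
    and builds the mirrored ("specular") ear plan, performs rigid surface
    registration (closed-form Kabsch fits and region-masked iterative closest
    point), solves cube fiducial-marker poses from pixel observations and
    composes the splint-anchored guidance transform chain, and evaluates
    postoperative scans against the plan via signed point-to-surface distance
    maps, region summaries and ear length/width morphometrics. Includes
    deterministic synthetic-data generators (parametric heads with ears,
    microtia cases, perturbed postoperative scans, marker observation scenes)
    so the full pipeline is testable without clinical data, plus a benchmark
    runner for deposited study models. Reads and writes STL (binary and
    ASCII), PLY and OBJ meshes and 3D Slicer markups FCSV landmark files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
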