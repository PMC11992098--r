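Package: tmaes
Title: Multi-Target Transcranial Magneto-Acoustic Electrical Stimulation Field Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of multi-target transcranial magneto-acoustic electrical
    stimulation (TMAES). Computes multi-focus delay laws for planar phased-array
    ultrasound transducers, steady-state focused pressure fields by free-field
    source summation over subdivided elements, and the electric field induced by
    magneto-acoustic (Lorentz-force) coupling under a static magnetic field.
    Provides focal-quality metrics (-3 dB focal regions and areas, axis lengths,
    peak separation, separation index R), frequency and magnetic-field sweep
    harnesses, YAML scenario configuration, exporters and a small command-line
    runner. All pipelines are deterministic and tibble-first.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    tibble,
    tidyr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
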