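Package: mitoclust
Title: Stochastic Simulation of MTOC Clustering and Nuclear Migration in Budding Yeast Mitosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coarse-grained three-dimensional agent-based model of early
    mitosis in a budding yeast with multiple cytoplasmic microtubule
    organizing centres (MTOCs). Cytoplasmic microtubules undergo dynamic
    instability, interact with a finite-width cell cortex (elastic push,
    collective dynein pull, wall impulse, Euler buckling, low-angle
    sliding), and transmit a Bim1-mediated tangential bias toward the
    septin ring. Forces move the nucleus, the envelope-embedded MTOCs and
    the kinetochores by overdamped (Stokes-drag) Euler dynamics. The
    package simulates MTOC fusion into the spindle pole body, SPB
    duplication, a minimal kinetochore-microtubule spindle, and
    mother-to-daughter nuclear migration; it reports per-cell event times,
    population summaries and dynein-density parameter scans for wild-type
    and perturbed (bim1 deletion, dynein overexpression, Ipl1-depletion)
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rlang,
    stats,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    yaml,
    jsonlite,
    generics,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
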