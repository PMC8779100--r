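Package: ramadyn
Title: Conformational-State and Relaxation Analysis of Polypeptide Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing backbone-dihedral trajectories of short
    polypeptides, in particular anionic homo-polypeptides such as
    poly(aspartic acid) and poly(glutamic acid). Provides Ramachandran
    region sets and per-residue conformational-state classification,
    population fractions with block-averaged errors, run-length statistics
    of equiconformational sequences, radius of gyration and end-to-end
    chain metrics, counterion-bridge detection, autocorrelation functions
    and stretched-exponential (Kohlrausch-Williams-Watts) relaxation fits,
    and a Markov-chain synthetic-trajectory generator for validating every
    stage of the pipeline without molecular-dynamics input. All functions
    take data frames and return tibbles so analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    minpack.lm,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
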