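Package: lgtratchet
Title: Wright-Fisher Simulation of Muller's Ratchet with Lateral Gene Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Forward-time Fisher-Wright simulation of a haploid population
    accumulating deleterious mutations under Muller's ratchet, with lateral
    gene transfer (transformation): uptake of environmental DNA from the
    previous generation followed by homologous recombination of a contiguous
    segment of L loci on a circular genome of g loci. Genome size and
    recombination length are explicit parameters. Tracks the least-loaded
    class, its extinction time, and genome-wide and per-locus fixation rates
    of deleterious mutations, with uniform or core/accessory selection
    regimes, seeded replicate runners, parameter sweeps, analytic
    mutation-selection-balance predictions, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
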