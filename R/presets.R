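#' Preset experiment specifications
#'
#' Ready-made [sweep_spec()]s for the four headline experiment families:
#'
#' * `"fig2"` — least-loaded-class extinction time (`Text`) as a function of
#'   genome size for several recombination lengths and LGT rates, constant
#'   per-locus mutation rate.
#' * `"fig3"` — genome-wide and per-locus fixation rates as a function of
#'   genome size, constant per-locus mutation rate.
#' * `"fig4"` — fixation rates with the genome-wide mutation rate held
#'   constant as genome size varies (isolates the intrinsic decline of LGT
#'   efficacy from the mutational-target effect).
#' * `"fig5-6"` — core/accessory selection regime: fixed-size strongly
#'   selected core (`g_core = 50`, `s_core = 0.005`) inside a weakly
#'   selected accessory genome (`s_accessory = 0.001`).
#'
#' Two scales are provided. `"paper"` records the full-scale captioned
#' parameter sets (`N = 5e3` or `1e4`, `s = 1e-3`, `mu = 1e-4`, 50
#' replicates, runs of 1e4-1e5 generations) — multi-hour computations meant
#' for cluster use. `"desk"` (default) preserves each experiment's
#' comparative structure at workstation scale: population size is reduced
#' about tenfold with the selection intensity `N*s` held at the full-scale
#' value (so `s = 0.01` at `N = 500` plays the role of `s = 1e-3` at
#' `N = 5e3`), the per-locus mutation rate is raised to `1e-3` so fixations
#' occur within shorter runs, and replicate counts are reduced. The desk
#' presets reproduce the qualitative orderings (extinction time falls with
#' genome size, LGT with long segments rescues large genomes, mutations
#' accumulate preferentially in the accessory genome), not the figures'
#' absolute values.
#'
#' @param name One of `"fig2"`, `"fig3"`, `"fig4"`, `"fig5-6"`.
#' @param scale `"desk"` (default) or `"paper"`.
#' @param base_seed Base seed for the sweep.
#' @param replicates,generations Optional overrides of the preset's
#'   replicate count and run length.
#' @return A [sweep_spec()].
#' @examples
#' desk_preset("fig2")
#' @export
desk_preset <- function(name = c("fig2", "fig3", "fig4", "fig5-6"),
                        scale = c("desk", "paper"), base_seed = 1,
                        replicates = NULL, generations = NULL) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  spec <- if (scale == "desk") {
    switch(name,
      "fig2" = sweep_spec(g = c(50, 100, 200), L = c("1", "5", "0.2g"),
                          lambda = c(0, 0.1), N = 500, mu = 1e-3, s = 0.01,
                          generations = 20000, replicates = 10,
                          base_seed = base_seed, stop_at_fixation = TRUE),
      "fig3" = sweep_spec(g = c(50, 100, 200), L = c("1", "5", "0.2g"),
                          lambda = c(0, 0.1), N = 500, mu = 1e-3, s = 0.01,
                          generations = 10000, replicates = 10,
                          base_seed = base_seed),
      "fig4" = sweep_spec(g = c(50, 100, 200), L = c("1", "5", "0.2g"),
                          lambda = c(0.01, 0.1), N = 500, U = 0.1, s = 0.01,
                          generations = 10000, replicates = 10,
                          base_seed = base_seed),
      "fig5-6" = sweep_spec(g = 100, L = c("5", "0.2g"), lambda = c(0, 0.1),
                            N = 200, mu = 1e-3, g_core = 50, s_core = 0.005,
                            s_accessory = 0.001, generations = 10000,
                            replicates = 10, base_seed = base_seed))
  } else {
    switch(name,
      "fig2" = sweep_spec(g = c(100, 250, 500, 1000, 2500),
                          L = c("1", "5", "10", "0.2g"),
                          lambda = c(0, 0.01, 0.1), N = 5000, mu = 1e-4,
                          s = 1e-3, generations = 10000, replicates = 50,
                          base_seed = base_seed, stop_at_fixation = TRUE),
      "fig3" = sweep_spec(g = c(100, 250, 500, 1000, 2500),
                          L = c("1", "5", "10", "0.2g"),
                          lambda = c(0, 0.01, 0.1), N = 10000, mu = 1e-4,
                          s = 1e-3, generations = 100000, replicates = 50,
                          base_seed = base_seed),
      "fig4" = sweep_spec(g = c(100, 250, 500, 1000, 2500),
                          L = c("1", "5", "10", "0.2g"),
                          lambda = c(0.01, 0.1), N = 5000, U = 0.1, s = 1e-3,
                          generations = 100000, replicates = 50,
                          base_seed = base_seed),
      "fig5-6" = sweep_spec(g = c(100, 500), L = c("5", "0.2g"),
                            lambda = c(0, 0.1), N = 10000, mu = 1e-4,
                            g_core = 50, s_core = 0.005, s_accessory = 0.001,
                            generations = 100000, replicates = 50,
                            base_seed = base_seed))
  }
  if (!is.null(replicates)) spec$replicates <- as.integer(replicates)
  if (!is.null(generations)) spec$generations <- as.integer(generations)
  spec$base_seed <- as.integer(base_seed)
  spec
}
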