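#' Equilibrium size of the least-loaded class
#'
#' Deterministic mutation-selection balance for a haploid population under
#' genome-wide deleterious mutation rate `U` and uniform selection `s`
#' predicts a Poisson load distribution whose mutation-free class contains
#' on average `n0 = N * exp(-U / s)` individuals. Because `U = mu * g` under
#' a constant per-locus mutation rate, `n0` declines exponentially with
#' genome size: the classic statement of why the ratchet bites harder in
#' larger genomes. When `n0` is small the ratchet clicks rapidly; the
#' simulation's time-averaged LLC size before the first click should match
#' `n0` up to sampling error.
#'
#' @param N Population size.
#' @param U Genome-wide deleterious mutation rate per generation.
#' @param s Selection coefficient per mutation (> 0).
#' @return Expected equilibrium number of mutation-free individuals.
#' @examples
#' equilibrium_llc_size(2000, 0.05, 0.05)  # 2000 * exp(-1) ~ 736
#' @export
equilibrium_llc_size <- function(N, U, s) {
  check_count(N, "N", min = 1)
  if (!is.numeric(U) || length(U) != 1 || is.na(U) || U < 0) {
    stop("`U` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(s) || length(s) != 1 || is.na(s) || s <= 0) {
    stop("`s` must be > 0: the mutation-selection equilibrium is undefined at s = 0",
         call. = FALSE)
  }
  N * exp(-U / s)
}

#' Predicted LLC equilibrium across genome sizes
#'
#' Tabulates [equilibrium_llc_size()] over a grid of genome sizes under the
#' constant per-locus mutation regime (`U = mu * g`), exposing the
#' exponential decline of ratchet resistance with genome size:
#' `log(n0)` is linear in `g` with slope `-mu / s`.
#'
#' @param N Population size.
#' @param mu Mutation rate per locus per generation.
#' @param s Selection coefficient per mutation (> 0).
#' @param g_values Vector of positive integer genome sizes.
#' @return A data.frame with columns `g`, `U`, `n0_expected`.
#' @examples
#' predicted_severity_curve(5000, 1e-4, 1e-3, c(100, 500, 1000))
#' @export
predicted_severity_curve <- function(N, mu, s, g_values) {
  if (!is.numeric(g_values) || length(g_values) < 1 || any(is.na(g_values)) ||
      any(g_values < 1) || any(g_values != as.integer(g_values))) {
    stop("`g_values` must be positive integers", call. = FALSE)
  }
  if (!is.numeric(mu) || length(mu) != 1 || is.na(mu) || mu < 0) {
    stop("`mu` must be a single non-negative number", call. = FALSE)
  }
  U <- mu * g_values
  data.frame(g = as.integer(g_values), U = U,
             n0_expected = vapply(U, function(u) equilibrium_llc_size(N, u, s),
                                  numeric(1)))
}
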