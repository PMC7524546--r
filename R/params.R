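#' Simulation parameters for the Wright-Fisher + LGT model
#'
#' Bundles and validates the rates and sizes of a single simulation run:
#' population size `N`, genome size `g` (number of loci on a circular
#' genome), the per-locus mutation rate `mu` and genome-wide rate `U`
#' (linked by `U = mu * g`), the LGT rate `lambda` (probability per
#' individual per generation of one transformation event), the recombination
#' length `L` (contiguous loci replaced per event), and the run length.
#'
#' Exactly one of `mu` and `U` needs to be supplied; the other is derived
#' from `U = mu * g`. The `mutation_regime` records which of the two is held
#' fixed when `g` is varied across a sweep: `"per_locus"` keeps `mu`
#' constant (so `U` grows with `g`), `"genome_wide"` keeps `U` constant (so
#' `mu = U / g` shrinks with `g`). When omitted it is inferred from which
#' rate was supplied.
#'
#' @param N Population size (integer >= 1). Constant through a run.
#' @param g Genome size: number of loci (integer >= 1).
#' @param mu Deleterious mutation rate per locus per generation (>= 0).
#' @param U Genome-wide deleterious mutation rate per generation (>= 0).
#' @param lambda Probability per individual per generation of undergoing one
#'   LGT event (in `[0, 1]`). At most one event per individual per
#'   generation.
#' @param L Recombination length: number of contiguous loci copied from the
#'   donor per LGT event (integer in `[1, g]`), or the fraction rule as a
#'   string such as `"0.2g"`, resolved via [resolve_L()].
#' @param generations Run length in generations (integer >= 1).
#' @param mutation_regime `"per_locus"` or `"genome_wide"`; see Details.
#' @param seed Optional integer RNG seed recorded with the parameters and
#'   used by [simulate_run()] when no explicit seed is given.
#'
#' @return An object of class `sim_params`: a validated list with fields
#'   `N`, `g`, `mu`, `U`, `mutation_regime`, `lambda`, `L`, `generations`,
#'   `seed`.
#' @examples
#' p <- sim_params(N = 5000, g = 100, mu = 1e-4, lambda = 0.1, L = "0.2g")
#' p$U   # 0.01 = mu * g
#' p$L   # 20
#' @seealso [fitness_model()], [simulate_run()]
#' @export
sim_params <- function(N, g, mu = NULL, U = NULL, lambda = 0, L = 1,
                       generations = 10000, mutation_regime = NULL,
                       seed = NULL) {
  check_count(N, "N", min = 1)
  check_count(g, "g", min = 1)
  check_count(generations, "generations", min = 1)
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("`lambda` must be a single probability in [0, 1]", call. = FALSE)
  }
  L <- resolve_L(L, g)
  if (L < 1 || L > g) {
    stop("`L` must lie in [1, g]; got L = ", L, " with g = ", g,
         call. = FALSE)
  }

  if (is.null(mu) && is.null(U)) {
    stop("one of `mu` or `U` must be supplied", call. = FALSE)
  }
  if (!is.null(mu) && (!is.numeric(mu) || length(mu) != 1 || is.na(mu) || mu < 0)) {
    stop("`mu` must be a single non-negative number", call. = FALSE)
  }
  if (!is.null(U) && (!is.numeric(U) || length(U) != 1 || is.na(U) || U < 0)) {
    stop("`U` must be a single non-negative number", call. = FALSE)
  }
  if (!is.null(mu) && !is.null(U) && U != mu * g) {
    stop("`mu` and `U` are inconsistent: U must equal mu * g (",
         mu * g, "), got ", U, call. = FALSE)
  }
  if (is.null(mutation_regime)) {
    mutation_regime <- if (is.null(U)) "per_locus" else "genome_wide"
  }
  mutation_regime <- match.arg(mutation_regime, c("per_locus", "genome_wide"))
  if (is.null(mu)) mu <- U / g
  if (is.null(U)) U <- mu * g

  if (!is.null(seed)) check_count(seed, "seed", min = 0)

  structure(
    list(N = as.integer(N), g = as.integer(g), mu = mu, U = U,
         mutation_regime = mutation_regime, lambda = lambda,
         L = as.integer(L), generations = as.integer(generations),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_params"
  )
}

#' Resolve a recombination length specification
#'
#' `L` may be given as an absolute number of loci or as a fraction rule tied
#' to genome size, written `"<frac>g"` (for example `"0.2g"`). The fraction
#' rule resolves to `max(1, round(frac * g))`, so it scales with the genome:
#' with `g = 2500`, `"0.2g"` resolves to 500 loci.
#'
#' @param L Numeric count of loci, or a string of the form `"0.2g"`.
#' @param g Genome size used to resolve the fraction rule.
#' @return Integer recombination length.
#' @examples
#' resolve_L("0.2g", 2500) # 500
#' resolve_L(5, 100)       # 5
#' @export
resolve_L <- function(L, g) {
  if (is.character(L)) {
    if (length(L) != 1 || !grepl("^[0-9.]+g$", L)) {
      stop("string `L` must have the form \"<fraction>g\", e.g. \"0.2g\"; got ",
           deparse(L), call. = FALSE)
    }
    frac <- as.numeric(sub("g$", "", L))
    return(as.integer(max(1, round(frac * g))))
  }
  if (!is.numeric(L) || length(L) != 1 || is.na(L) || L != as.integer(L)) {
    stop("`L` must be a whole number of loci or a fraction rule string",
         call. = FALSE)
  }
  as.integer(L)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop("`", name, "` must be a single integer >= ", min, "; got ",
         deparse(x), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Wright-Fisher + LGT simulation parameters\n")
  cat(sprintf("  N = %d individuals, g = %d loci (circular)\n", x$N, x$g))
  cat(sprintf("  mu = %g per locus, U = %g genome-wide (%s regime)\n",
              x$mu, x$U, x$mutation_regime))
  cat(sprintf("  lambda = %g per individual per generation, L = %d loci\n",
              x$lambda, x$L))
  cat(sprintf("  run length = %d generations%s\n", x$generations,
              if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  invisible(x)
}
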