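#' Selection model: per-locus coefficients and fitness-function form
#'
#' Describes how deleterious mutations translate into reproductive fitness.
#' Two functional forms are available for an individual carrying `z_i`
#' mutations at locus `i`:
#'
#' * `"linear"` (default): `w = max(0, 1 - sum_i s_i * z_i)`. With a uniform
#'   coefficient `s` this is the classic no-epistasis load formula
#'   `w_m = 1 - s m`, where `m` is the individual's total mutation count.
#' * `"multiplicative"`: `w = prod_i (1 - s_i)^{z_i}`, i.e. every mutation
#'   multiplies fitness by `(1 - s_i)`.
#'
#' For the selection strengths typical of this model (`s <= 0.005`) the two
#' forms agree to first order in `s m`.
#'
#' Selection may be uniform (every locus has the same `s`) or split between
#' a strongly selected core genome and a weakly selected accessory genome.
#' In the core/accessory regime, `g_core` loci carry `s_core` and the
#' remaining `g - g_core` carry `s_accessory`. Which loci are core is either
#' supplied explicitly through `core_mask` or sampled uniformly without
#' replacement — once per replicate, from the replicate's RNG stream — when
#' `core_mask` is left `NULL` (see [realize_core_mask()]).
#'
#' @param g Genome size (number of loci).
#' @param s Uniform selection coefficient per mutation, or a full length-`g`
#'   vector of per-locus coefficients. Ignored when `g_core > 0`.
#' @param form `"linear"` or `"multiplicative"`.
#' @param g_core Number of core loci (0 for a uniform model).
#' @param s_core Selection coefficient at core loci (default 0.005).
#' @param s_accessory Selection coefficient at accessory loci (default 0.001).
#' @param core_mask Optional logical vector of length `g` with exactly
#'   `g_core` `TRUE` entries marking the core loci. `NULL` defers the random
#'   placement to [realize_core_mask()].
#' @return An object of class `fitness_model` with fields `form`,
#'   `s_per_locus` (NULL until the core mask is realized in the
#'   core/accessory regime), `core_mask`, `g_core`, `s_core`, `s_accessory`,
#'   `g`.
#' @examples
#' uniform <- fitness_model(g = 100, s = 1e-3)
#' split <- fitness_model(g = 100, g_core = 50)  # s 0.005 core / 0.001 accessory
#' @export
fitness_model <- function(g, s = NULL, form = c("linear", "multiplicative"),
                          g_core = 0, s_core = 0.005, s_accessory = 0.001,
                          core_mask = NULL) {
  form <- match.arg(form)
  check_count(g, "g", min = 1)
  check_count(g_core, "g_core", min = 0)
  if (g_core > g) stop("`g_core` cannot exceed g", call. = FALSE)

  check_s <- function(v, name) {
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v > 1)) {
      stop("`", name, "` must lie in [0, 1]", call. = FALSE)
    }
    if (form == "multiplicative" && any(v >= 1)) {
      stop("`", name, "` must be < 1 under the multiplicative form",
           call. = FALSE)
    }
  }

  if (g_core > 0) {
    check_s(s_core, "s_core")
    check_s(s_accessory, "s_accessory")
    if (!is.null(core_mask)) {
      if (!is.logical(core_mask) || length(core_mask) != g ||
          anyNA(core_mask)) {
        stop("`core_mask` must be a logical vector of length g", call. = FALSE)
      }
      if (sum(core_mask) != g_core) {
        stop("`core_mask` must have exactly g_core TRUE entries", call. = FALSE)
      }
    }
    s_per_locus <- if (is.null(core_mask)) NULL else
      ifelse(core_mask, s_core, s_accessory)
  } else {
    if (is.null(s)) stop("uniform model needs `s`", call. = FALSE)
    if (!length(s) %in% c(1L, g)) {
      stop("`s` must be a scalar or a length-g vector", call. = FALSE)
    }
    check_s(s, "s")
    s_per_locus <- rep_len(as.numeric(s), g)
    core_mask <- rep(FALSE, g)
  }

  structure(
    list(form = form, s_per_locus = s_per_locus, core_mask = core_mask,
         g_core = as.integer(g_core), s_core = if (g_core > 0) s_core else NA_real_,
         s_accessory = if (g_core > 0) s_accessory else NA_real_,
         g = as.integer(g)),
    class = "fitness_model"
  )
}

#' Draw the random core/accessory locus assignment
#'
#' In the core/accessory regime the identity of the core loci is random:
#' `g_core` locus indices are sampled uniformly without replacement from the
#' current RNG stream. A model whose mask is already set (explicitly, or by a
#' previous call) is returned unchanged, so each replicate draws its
#' placement exactly once.
#'
#' @param fm A [fitness_model()].
#' @return The model with `core_mask` and `s_per_locus` filled in.
#' @export
realize_core_mask <- function(fm) {
  stopifnot(inherits(fm, "fitness_model"))
  if (fm$g_core == 0 || !is.null(fm$s_per_locus)) return(fm)
  mask <- rep(FALSE, fm$g)
  mask[sample.int(fm$g, fm$g_core)] <- TRUE
  fm$core_mask <- mask
  fm$s_per_locus <- ifelse(mask, fm$s_core, fm$s_accessory)
  fm
}

#' Reproductive fitness of every individual
#'
#' Evaluates the fitness function of a [fitness_model()] on the current
#' population: one value per individual, in `[0, 1]`, with mutation-free
#' genomes at exactly 1. See [fitness_model()] for the two functional forms.
#'
#' @param state A [population_state()].
#' @param fm A [fitness_model()] with its per-locus coefficients resolved
#'   (see [realize_core_mask()]); genome sizes must match.
#' @return Numeric vector of `N` fitness values.
#' @examples
#' p <- sim_params(N = 4, g = 10, mu = 0)
#' st <- init_population(p)
#' compute_fitness(st, fitness_model(g = 10, s = 1e-3))  # all 1
#' @export
compute_fitness <- function(state, fm) {
  stopifnot(inherits(state, "population_state"), inherits(fm, "fitness_model"))
  g <- ncol(state$counts)
  if (g != fm$g) {
    stop("genome size mismatch: state has g = ", g, ", fitness model g = ",
         fm$g, call. = FALSE)
  }
  if (is.null(fm$s_per_locus)) {
    stop("core/accessory placement not yet drawn; call realize_core_mask()",
         call. = FALSE)
  }
  fitness_from_counts(state$counts, fm$s_per_locus, fm$form)
}

# Column-outer accumulation in plain double precision, mirroring the C++
# engine operation-for-operation so the two trajectories are bit-identical.
fitness_from_counts <- function(counts, s, form) {
  n <- nrow(counts)
  acc <- numeric(n)
  if (form == "multiplicative") {
    lg <- log1p(-s)
    for (i in seq_len(ncol(counts))) acc <- acc + counts[, i] * lg[i]
    exp(acc)
  } else {
    for (i in seq_len(ncol(counts))) acc <- acc + counts[, i] * s[i]
    pmax(0, 1 - acc)
  }
}

#' @export
print.fitness_model <- function(x, ...) {
  cat("Fitness model (", x$form, " form)\n", sep = "")
  if (x$g_core > 0) {
    cat(sprintf("  core/accessory regime: g = %d, g_core = %d (s_core = %g, s_accessory = %g)\n",
                x$g, x$g_core, x$s_core, x$s_accessory))
    if (is.null(x$s_per_locus)) {
      cat("  core placement not yet drawn (sampled per replicate)\n")
    }
  } else {
    cat(sprintf("  uniform selection: g = %d, s = %g\n", x$g, x$s_per_locus[1]))
  }
  invisible(x)
}
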