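#' Population state: per-locus mutation counts
#'
#' The state of the population at one generation is the `N x g` integer
#' matrix of per-locus deleterious mutation counts: `counts[j, i]` is the
#' number of mutations carried at locus `i` by individual `j`. Loci are
#' arranged on a circular genome (locus `g` is adjacent to locus 1) and
#' counts can exceed 1 because a locus may be hit repeatedly. The matrix
#' dimensions never change during a run.
#'
#' @param counts Non-negative integer matrix (`N` rows, `g` columns).
#' @param generation Generation index `t >= 0`.
#' @return An object of class `population_state`.
#' @export
population_state <- function(counts, generation = 0L) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be an integer matrix", call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != as.integer(counts))) {
    stop("`counts` entries must be non-negative integers", call. = FALSE)
  }
  check_count(generation, "generation", min = 0)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, generation = as.integer(generation)),
            class = "population_state")
}

#' Mutation-free initial population
#'
#' Runs start from a population entirely free of mutation: an all-zero
#' `N x g` count matrix at generation 0, so the least-loaded class initially
#' contains all `N` individuals.
#'
#' @param params A [sim_params()] object.
#' @return A [population_state()] with all counts zero and `generation = 0`.
#' @examples
#' st <- init_population(sim_params(N = 3, g = 4, mu = 0))
#' st$counts
#' @export
init_population <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  population_state(matrix(0L, nrow = params$N, ncol = params$g), 0L)
}

#' Fitness-proportional reproduction (Wright-Fisher sampling)
#'
#' Forms the next generation by sampling `N` parents with replacement, each
#' drawn with probability proportional to its fitness, and copying their
#' genomes. The parent matrix is left untouched: the old generation dies and
#' its genomes become the eDNA donor pool for the offspring's LGT step.
#'
#' Sampling is by inversion of the cumulative fitness profile against `N`
#' uniform draws, so the parent choice is reproducible across the R and C++
#' engines for a fixed seed.
#'
#' @param state Current [population_state()].
#' @param fitness Numeric vector of `N` non-negative fitness values, at
#'   least one positive.
#' @return A new [population_state()] of offspring, `generation` advanced
#'   by one.
#' @section Extinction: if every fitness is zero the population cannot
#'   reproduce; an error of class `lgtratchet_extinct` is thrown, which
#'   [simulate_run()] converts into a flagged replicate outcome.
#' @export
selection_step <- function(state, fitness) {
  stopifnot(inherits(state, "population_state"))
  n <- nrow(state$counts)
  if (length(fitness) != n || any(is.na(fitness)) || any(fitness < 0)) {
    stop("`fitness` must be a non-negative vector of length N", call. = FALSE)
  }
  cw <- cumsum(fitness)
  tot <- cw[n]
  if (tot <= 0) {
    stop(structure(class = c("lgtratchet_extinct", "error", "condition"),
                   list(message = "population extinct: all fitness values are zero",
                        call = sys.call(-1))))
  }
  x <- runif(n) * tot
  parents <- pmin(findInterval(x, cw, left.open = TRUE) + 1L, n)
  population_state(state$counts[parents, , drop = FALSE],
                   state$generation + 1L)
}

#' Poisson mutation
#'
#' Each individual `j` acquires `n(j) ~ Poisson(U)` new deleterious
#' mutations per generation, where `U = mu * g` is the genome-wide rate;
#' each mutation lands on a locus drawn uniformly (with replacement, so one
#' locus can be hit more than once). Counts never decrease. For small `mu`
#' this is equivalent to each locus mutating independently with
#' probability `mu`.
#'
#' @param state A [population_state()].
#' @param params A [sim_params()]; only `U` and `g` are used.
#' @return The state with mutations added (generation index unchanged).
#' @export
mutation_step <- function(state, params) {
  stopifnot(inherits(state, "population_state"), inherits(params, "sim_params"))
  counts <- state$counts
  n <- nrow(counts)
  g <- ncol(counts)
  nmut <- rpois(n, params$U)
  total <- sum(nmut)
  if (total > 0) {
    loci <- pmin(floor(runif(total) * g) + 1L, g)
    rows <- rep(seq_len(n), nmut)
    idx <- rows + (loci - 1L) * n
    ui <- unique(idx)
    counts[ui] <- counts[ui] + tabulate(match(idx, ui), nbins = length(ui))
    state$counts <- counts
  }
  state
}

#' Lateral gene transfer (transformation) of eDNA segments
#'
#' Each individual independently undergoes at most one LGT event per
#' generation, with probability `lambda`. On an event, a donor genome is
#' drawn uniformly from the previous generation's end-of-life genomes (the
#' eDNA pool, which persists exactly one generation), a start locus is drawn
#' uniformly on the circular genome, and the `L` contiguous loci from the
#' start (wrapping from locus `g` to locus 1) are copied from donor to
#' recipient at the same coordinates, overwriting the recipient's counts
#' there. The recipient's mutation load can go up or down.
#'
#' @param state Recipient [population_state()].
#' @param donor_pool [population_state()] holding the previous generation's
#'   final genomes; same genome size, at least one row.
#' @param params A [sim_params()]; uses `lambda` and `L`.
#' @return The state after recombination (generation index unchanged).
#' @export
lgt_step <- function(state, donor_pool, params) {
  stopifnot(inherits(state, "population_state"),
            inherits(donor_pool, "population_state"),
            inherits(params, "sim_params"))
  g <- ncol(state$counts)
  if (ncol(donor_pool$counts) != g) {
    stop("donor pool genome size differs from recipients", call. = FALSE)
  }
  nd <- nrow(donor_pool$counts)
  if (nd < 1) stop("empty donor pool", call. = FALSE)
  if (params$L > g) stop("`L` exceeds genome size", call. = FALSE)
  if (params$lambda == 0) return(state)

  n <- nrow(state$counts)
  u <- runif(n)
  events <- which(u < params$lambda)
  for (j in events) {
    donor <- min(floor(runif(1) * nd) + 1L, nd)
    start <- min(floor(runif(1) * g) + 1L, g)
    seg <- ((start - 1L + seq_len(params$L) - 1L) %% g) + 1L
    state$counts[j, seg] <- donor_pool$counts[donor, seg]
  }
  state
}

#' One full generation of the life cycle
#'
#' Applies, in order: fitness evaluation of the current generation,
#' fitness-proportional [selection_step()], Poisson [mutation_step()], and
#' [lgt_step()] with the parent generation's final genomes as the eDNA donor
#' pool. Per-generation statistics (least-loaded-class size, mean load,
#' per-locus fixed-mutation minima) are measured after recombination, the
#' point at which a positive per-locus minimum is provably irreversible.
#'
#' This is the Materials-and-methods ordering of the life cycle; the
#' alternative ordering in which the newborn generation recombines and
#' mutates before reproducing is available through
#' `simulate_run(event_order = "figure1")`.
#'
#' @param state Current [population_state()].
#' @param params A [sim_params()].
#' @param fm A resolved [fitness_model()].
#' @return A list with elements `state` (the offspring generation) and
#'   `stats` (a one-row data.frame: `generation`, `llc_size`, `mean_load`,
#'   `fixed_total`).
#' @export
advance_generation <- function(state, params, fm) {
  w <- compute_fitness(state, fm)
  offspring <- selection_step(state, w)
  offspring <- mutation_step(offspring, params)
  offspring <- lgt_step(offspring, donor_pool = state, params)
  list(state = offspring, stats = generation_stats(offspring))
}

generation_stats <- function(state) {
  counts <- state$counts
  loads <- rowSums(counts)
  llc <- sum(loads == 0L)
  fixed_total <- if (llc > 0L) 0L else sum(fixed_mutation_vector(state))
  data.frame(generation = state$generation, llc_size = llc,
             mean_load = mean(loads), fixed_total = fixed_total)
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("Population state: %d individuals x %d loci, generation %d\n",
              nrow(x$counts), ncol(x$counts), x$generation))
  cat(sprintf("  least-loaded class: %d individuals; mean load %.3f\n",
              llc_size(x), mean(rowSums(x$counts))))
  invisible(x)
}
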