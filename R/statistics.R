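#' Size of the least-loaded class
#'
#' The least-loaded class (LLC) is the set of individuals whose genomes are
#' entirely mutation free (all-zero count rows). Its size, and in particular
#' the time at which it is irreversibly lost, measures the severity of
#' Muller's ratchet.
#'
#' @param state A [population_state()].
#' @return Integer count of mutation-free individuals, in `[0, N]`.
#' @export
llc_size <- function(state) {
  stopifnot(inherits(state, "population_state"))
  sum(rowSums(state$counts) == 0L)
}

#' Per-locus fixed mutation levels
#'
#' For each locus `i`, the number of mutation levels fixed in the whole
#' population: `min_j counts[j, i]`. A locus is fixed for the mutant iff its
#' minimum is at least 1 — the zero-count (wild-type) class at that locus is
#' lost. If any individual is mutation free the vector is identically zero.
#'
#' @param state A [population_state()].
#' @return Integer vector of length `g` of column minima.
#' @export
fixed_mutation_vector <- function(state) {
  stopifnot(inherits(state, "population_state"))
  apply(state$counts, 2, min)
}

#' Per-locus fixation tracker
#'
#' Accumulates, across the generations of one run, the first generation at
#' which each locus irreversibly lost its wild-type class, the current
#' per-locus fixed mutation levels, and `text` — the generation of the first
#' fixation anywhere in the genome, i.e. the extinction time of the
#' least-loaded class. Because back-mutation is absent and the eDNA pool is
#' drawn from the previous generation, a fixation observed after the
#' recombination step can never be undone, so recorded fixations are
#' permanent.
#'
#' @param g Genome size.
#' @return An object of class `fixation_tracker` with fields
#'   `first_fixation_generation` (integer vector, `NA` = not yet fixed),
#'   `fixed_mutation_count` (current per-locus minima), `text` (`NA` until
#'   the first fixation), `last_generation`.
#' @seealso [update_fixation_tracker()], [fixation_rates()]
#' @export
new_fixation_tracker <- function(g) {
  check_count(g, "g", min = 1)
  structure(
    list(first_fixation_generation = rep(NA_integer_, g),
         fixed_mutation_count = integer(g),
         text = NA_integer_,
         last_generation = NA_integer_),
    class = "fixation_tracker"
  )
}

#' Record fixations for the current generation
#'
#' Called once per generation, after the LGT step, with the generation's
#' final state. Records the first-fixation generation for any locus whose
#' per-locus minimum became positive for the first time, refreshes the
#' fixed-level counts, and sets `text` on the first fixation event anywhere
#' in the genome.
#'
#' @param tracker A [new_fixation_tracker()].
#' @param state The generation's final [population_state()].
#' @return The updated tracker.
#' @export
update_fixation_tracker <- function(tracker, state) {
  stopifnot(inherits(tracker, "fixation_tracker"),
            inherits(state, "population_state"))
  gen <- state$generation
  if (!is.na(tracker$last_generation) && gen < tracker$last_generation) {
    stop("generation index decreased: tracker last saw generation ",
         tracker$last_generation, ", got ", gen, call. = FALSE)
  }
  minima <- fixed_mutation_vector(state)
  newly <- which(minima >= 1L & is.na(tracker$first_fixation_generation))
  if (length(newly) > 0) {
    tracker$first_fixation_generation[newly] <- gen
    if (is.na(tracker$text)) tracker$text <- gen
  }
  tracker$fixed_mutation_count <- as.integer(minima)
  tracker$last_generation <- as.integer(gen)
  tracker
}

#' Genome-wide and per-locus fixation rates
#'
#' The genome-wide rate of fixation of deleterious mutations is the total
#' number of fixed mutations at the end of the run divided by the elapsed
#' generations; the per-locus rate divides it further by genome size `g`,
#' so `per_locus_rate * g = genome_wide_rate` exactly.
#'
#' @param tracker A [fixation_tracker][new_fixation_tracker()] at end of run.
#' @param elapsed_generations Run duration (>= 1).
#' @param g Genome size.
#' @param count `"levels"` (default) counts every fixed mutation level —
#'   `sum_i min_j counts[j, i]` — so a locus that fixes repeatedly over a
#'   long run contributes each level; `"loci"` counts each fixed locus once.
#' @return Named list `genome_wide_rate`, `per_locus_rate`.
#' @export
fixation_rates <- function(tracker, elapsed_generations, g,
                           count = c("levels", "loci")) {
  stopifnot(inherits(tracker, "fixation_tracker"))
  count <- match.arg(count)
  check_count(g, "g", min = 1)
  if (!is.numeric(elapsed_generations) || length(elapsed_generations) != 1 ||
      is.na(elapsed_generations) || elapsed_generations < 1) {
    stop("`elapsed_generations` must be >= 1", call. = FALSE)
  }
  total <- if (count == "levels") sum(tracker$fixed_mutation_count)
           else sum(tracker$fixed_mutation_count >= 1L)
  gw <- total / elapsed_generations
  list(genome_wide_rate = gw, per_locus_rate = gw / g)
}

#' Fixed mutations split by core vs accessory genome
#'
#' Splits the tracker's fixed mutation levels between the core and
#' accessory compartments of a core/accessory [fitness_model()] and reports
#' each compartment's per-locus fixation rate, normalising each count by
#' that compartment's own locus number (so the two compartments are
#' comparable per locus). Set `normalise = "total_g"` to normalise both by
#' the whole genome size instead. An empty compartment's rate is `NA`.
#'
#' @param tracker A [fixation_tracker][new_fixation_tracker()].
#' @param fm A [fitness_model()] with a resolved `core_mask`.
#' @param elapsed_generations Run duration (>= 1).
#' @param normalise `"compartment"` (default) or `"total_g"`.
#' @return A data.frame with one row per compartment: `compartment`,
#'   `n_loci`, `fixed_count`, `per_locus_rate`.
#' @export
compartment_fixation_summary <- function(tracker, fm, elapsed_generations,
                                         normalise = c("compartment", "total_g")) {
  stopifnot(inherits(tracker, "fixation_tracker"),
            inherits(fm, "fitness_model"))
  normalise <- match.arg(normalise)
  if (is.null(fm$core_mask)) {
    stop("fitness model has no resolved core_mask", call. = FALSE)
  }
  if (length(fm$core_mask) != length(tracker$fixed_mutation_count)) {
    stop("genome size mismatch between tracker and fitness model",
         call. = FALSE)
  }
  mask <- fm$core_mask
  counts <- c(core = sum(tracker$fixed_mutation_count[mask]),
              accessory = sum(tracker$fixed_mutation_count[!mask]))
  n_loci <- c(core = sum(mask), accessory = sum(!mask))
  denom <- if (normalise == "compartment") n_loci else
    rep(length(mask), 2)
  rate <- ifelse(n_loci == 0, NA_real_,
                 counts / (denom * elapsed_generations))
  data.frame(compartment = c("core", "accessory"),
             n_loci = as.integer(n_loci),
             fixed_count = as.integer(counts),
             per_locus_rate = rate,
             row.names = NULL)
}

#' @export
print.fixation_tracker <- function(x, ...) {
  nfix <- sum(!is.na(x$first_fixation_generation))
  cat(sprintf("Fixation tracker: %d/%d loci fixed, %d fixed mutation levels\n",
              nfix, length(x$fixed_mutation_count),
              sum(x$fixed_mutation_count)))
  if (is.na(x$text)) {
    cat("  least-loaded class not yet irreversibly lost (Text censored)\n")
  } else {
    cat(sprintf("  first fixation (Text) at generation %d\n", x$text))
  }
  invisible(x)
}
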