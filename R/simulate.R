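#' Run one replicate of the Wright-Fisher + LGT model
#'
#' Simulates a single population trajectory from a mutation-free start,
#' tracking per generation the least-loaded-class (LLC) size, the mean
#' mutation load, and the total fixed mutation levels, and recording the
#' first-fixation generation of every locus. The extinction time of the LLC
#' (`text`) is the generation of the first irreversible fixation anywhere in
#' the genome; a run with no fixation is censored at its run length.
#'
#' Two engines produce bit-identical trajectories for a fixed seed: the
#' compiled engine (`"cpp"`, default, used for production runs) and the pure
#' R reference built from [advance_generation()] and the individual step
#' functions (`"r"`, used for validation; it can also retain the full state
#' history for brute-force cross-checks).
#'
#' @param params A [sim_params()].
#' @param fm A [fitness_model()]; a core/accessory model without a resolved
#'   mask has its core loci drawn from this replicate's RNG stream.
#' @param seed Integer seed; falls back to `params$seed`; `NULL` leaves the
#'   RNG stream untouched.
#' @param engine `"cpp"` or `"r"`.
#' @param stop_at_fixation Stop the run at the generation of the first
#'   fixation (useful when only `text` is needed).
#' @param event_order `"methods"` (selection -> mutation -> LGT, the
#'   default) or `"figure1"` (LGT -> mutation -> selection); statistics are
#'   measured after the recombination step in both orders.
#' @param keep_history (R engine only) store every generation's count
#'   matrix; used by brute-force verification on tiny instances.
#' @return An object of class `wf_run`: list with the per-generation vectors
#'   `llc_size`, `mean_load`, `fixed_total`; the [fixation
#'   tracker][new_fixation_tracker()]; `text`, `censored`, `extinct`,
#'   `generations_run`; the resolved `params` and `fm`; the final
#'   [population_state()]; and (optionally) `history`.
#' @examples
#' p <- sim_params(N = 50, g = 20, mu = 2e-3, lambda = 0.1, L = 4,
#'                 generations = 200)
#' run <- simulate_run(p, fitness_model(g = 20, s = 0.01), seed = 1)
#' run$text
#' @export
simulate_run <- function(params, fm, seed = NULL,
                         engine = c("cpp", "r"),
                         stop_at_fixation = FALSE,
                         event_order = c("methods", "figure1"),
                         keep_history = FALSE) {
  stopifnot(inherits(params, "sim_params"), inherits(fm, "fitness_model"))
  engine <- match.arg(engine)
  event_order <- match.arg(event_order)
  if (fm$g != params$g) {
    stop("fitness model genome size differs from simulation parameters",
         call. = FALSE)
  }
  if (is.null(seed)) seed <- params$seed
  if (!is.null(seed)) set.seed(seed)
  fm <- realize_core_mask(fm)

  if (engine == "cpp") {
    raw <- wf_run_cpp(matrix(0L, params$N, params$g), fm$s_per_locus,
                      fm$form == "multiplicative", params$U, params$lambda,
                      params$L, params$generations, stop_at_fixation,
                      event_order == "figure1")
    tracker <- structure(
      list(first_fixation_generation = raw$first_fixation_generation,
           fixed_mutation_count = raw$fixed_mutation_count,
           text = raw$text,
           last_generation = raw$generations_run),
      class = "fixation_tracker")
    out <- list(llc_size = raw$llc_size, mean_load = raw$mean_load,
                fixed_total = raw$fixed_total, tracker = tracker,
                text = raw$text, extinct = raw$extinct,
                generations_run = raw$generations_run,
                final_state = population_state(raw$final_counts,
                                               max(raw$generations_run, 0L)),
                history = NULL)
  } else {
    out <- simulate_run_r(params, fm, stop_at_fixation, event_order,
                          keep_history)
  }

  out$censored <- is.na(out$text)
  out$params <- params
  out$fm <- fm
  out$engine <- engine
  out$event_order <- event_order
  out$seed <- seed
  class(out) <- "wf_run"
  out
}

# Pure-R reference engine: drives the exported step functions.
simulate_run_r <- function(params, fm, stop_at_fixation, event_order,
                           keep_history) {
  gens <- params$generations
  state <- init_population(params)
  tracker <- new_fixation_tracker(params$g)
  llc <- integer(gens)
  mload <- numeric(gens)
  ftot <- integer(gens)
  history <- if (keep_history) vector("list", gens) else NULL
  extinct <- FALSE
  t_done <- 0L
  pool <- state # figure1 order: previous generation's end-of-life genomes

  for (t in seq_len(gens)) {
    if (event_order == "figure1") {
      state <- lgt_step(state, pool, params)
      measured <- population_state(state$counts, t)
      st <- generation_stats(measured)
    } else {
      res <- tryCatch(advance_generation(state, params, fm),
                      lgtratchet_extinct = function(e) e)
      if (inherits(res, "lgtratchet_extinct")) {
        extinct <- TRUE
        break
      }
      state <- res$state
      measured <- state
      st <- res$stats
    }

    llc[t] <- st$llc_size
    mload[t] <- st$mean_load
    ftot[t] <- st$fixed_total
    tracker <- update_fixation_tracker(tracker, measured)
    if (keep_history) history[[t]] <- measured$counts
    t_done <- t
    last <- (stop_at_fixation && !is.na(tracker$text)) || t == gens

    if (event_order == "figure1" && !last) {
      state <- mutation_step(state, params)
      pool <- state
      w <- compute_fitness(state, fm)
      sel <- tryCatch(selection_step(state, w),
                      lgtratchet_extinct = function(e) e)
      if (inherits(sel, "lgtratchet_extinct")) {
        extinct <- TRUE
        break
      }
      state <- sel
    }
    if (last) break
  }

  list(llc_size = llc[seq_len(t_done)], mean_load = mload[seq_len(t_done)],
       fixed_total = ftot[seq_len(t_done)], tracker = tracker,
       text = tracker$text, extinct = extinct, generations_run = t_done,
       final_state = population_state(state$counts, t_done),
       history = if (keep_history) history[seq_len(t_done)] else NULL)
}

#' Summarise one replicate as a tidy row
#'
#' Collapses a [simulate_run()] result into a one-row data.frame: the
#' parameter echo, the replicate seed, `text` with its censoring flag (a
#' censored run reports its run length as a lower bound in
#' `text_effective`), the genome-wide and per-locus fixation rates, and —
#' for core/accessory models — each compartment's fixed counts and
#' per-locus rates.
#'
#' @param run A `wf_run` object.
#' @param replicate Optional replicate id echoed into the row.
#' @return A one-row data.frame.
#' @export
run_summary <- function(run, replicate = NA_integer_) {
  stopifnot(inherits(run, "wf_run"))
  p <- run$params
  elapsed <- max(run$generations_run, 1L)
  rates <- fixation_rates(run$tracker, elapsed, p$g)
  row <- data.frame(
    replicate = as.integer(replicate),
    seed = if (is.null(run$seed)) NA_integer_ else as.integer(run$seed),
    N = p$N, g = p$g, mu = p$mu, U = p$U, lambda = p$lambda, L = p$L,
    mutation_regime = p$mutation_regime,
    generations = p$generations,
    duration = run$generations_run,
    extinct = run$extinct,
    text = if (is.na(run$text)) NA_integer_ else as.integer(run$text),
    censored = run$censored,
    text_effective = if (is.na(run$text)) run$generations_run
                     else as.integer(run$text),
    fixed_total = sum(run$tracker$fixed_mutation_count),
    rate_genome = rates$genome_wide_rate,
    rate_per_locus = rates$per_locus_rate,
    stringsAsFactors = FALSE
  )
  if (run$fm$g_core > 0) {
    comp <- compartment_fixation_summary(run$tracker, run$fm, elapsed)
    row$core_fixed <- comp$fixed_count[comp$compartment == "core"]
    row$accessory_fixed <- comp$fixed_count[comp$compartment == "accessory"]
    row$core_rate <- comp$per_locus_rate[comp$compartment == "core"]
    row$accessory_rate <- comp$per_locus_rate[comp$compartment == "accessory"]
  } else {
    row$core_fixed <- NA_integer_
    row$accessory_fixed <- NA_integer_
    row$core_rate <- NA_real_
    row$accessory_rate <- NA_real_
  }
  row
}

#' @export
print.wf_run <- function(x, ...) {
  cat(sprintf("Wright-Fisher + LGT run (%s engine, %s order): %d generations\n",
              x$engine, x$event_order, x$generations_run))
  if (x$extinct) cat("  population went extinct (all fitness zero)\n")
  if (is.na(x$text)) {
    cat("  no fixation: Text censored at run length\n")
  } else {
    cat(sprintf("  Text = %d (first irreversible fixation)\n", x$text))
  }
  cat(sprintf("  fixed mutation levels at end: %d; final LLC size: %d\n",
              sum(x$tracker$fixed_mutation_count),
              if (x$generations_run > 0) x$llc_size[x$generations_run]
              else x$params$N))
  invisible(x)
}
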