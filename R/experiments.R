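#' Run independent seeded replicates of one parameter set
#'
#' Replicate `i` runs with seed `base_seed + i - 1`, so a batch is fully
#' deterministic given its base seed, and core/accessory locus placement is
#' redrawn from each replicate's own stream. Extinct replicates are flagged
#' in their summary row, not dropped.
#'
#' @param params A [sim_params()].
#' @param fm A [fitness_model()].
#' @param replicates Number of replicates (>= 1).
#' @param base_seed Integer base seed.
#' @param engine,stop_at_fixation,event_order Passed to [simulate_run()].
#' @param detail If `TRUE`, also return the full `wf_run` objects.
#' @param progress Emit a message per replicate.
#' @return A data.frame of [run_summary()] rows (one per replicate), or,
#'   with `detail = TRUE`, a list with elements `summaries` and `runs`.
#' @examples
#' p <- sim_params(N = 50, g = 10, mu = 1e-3, generations = 200)
#' run_replicates(p, fitness_model(g = 10, s = 0.01), replicates = 3,
#'                base_seed = 42)
#' @export
run_replicates <- function(params, fm, replicates, base_seed,
                           engine = c("cpp", "r"), stop_at_fixation = FALSE,
                           event_order = c("methods", "figure1"),
                           detail = FALSE, progress = FALSE) {
  check_count(replicates, "replicates", min = 1)
  check_count(base_seed, "base_seed", min = 0)
  if (base_seed + replicates - 1 >= 2^31) {
    stop("`base_seed` too large: replicate seeds must stay below 2^31",
         call. = FALSE)
  }
  engine <- match.arg(engine)
  event_order <- match.arg(event_order)

  runs <- vector("list", replicates)
  rows <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    seed_i <- as.integer(base_seed + i - 1)
    run <- tryCatch(
      simulate_run(params, fm, seed = seed_i, engine = engine,
                   stop_at_fixation = stop_at_fixation,
                   event_order = event_order),
      error = function(e) {
        stop("replicate ", i, " (seed ", seed_i, "): ",
             conditionMessage(e), call. = FALSE)
      })
    rows[[i]] <- run_summary(run, replicate = i)
    if (detail) runs[[i]] <- run
    if (progress) {
      message(sprintf("replicate %d/%d (seed %d): duration %d, Text %s, fixed %d",
                      i, replicates, seed_i, run$generations_run,
                      if (is.na(run$text)) "censored" else run$text,
                      sum(run$tracker$fixed_mutation_count)))
    }
  }
  summaries <- do.call(rbind, rows)
  rownames(summaries) <- NULL
  if (detail) list(summaries = summaries, runs = runs) else summaries
}

#' Aggregate replicate summaries (mean and SD per grid point)
#'
#' Collapses the tidy per-replicate table to one row per parameter
#' combination with means and standard deviations over the replicates of
#' `text_effective` (censored replicates enter at their run length, a lower
#' bound), the fixation rates, and — where present — the core/accessory
#' per-locus rates, plus the censoring fraction.
#'
#' @param df A data.frame of [run_summary()] rows.
#' @param by Grouping columns.
#' @return A data.frame with one row per group.
#' @export
aggregate_replicates <- function(df, by = c("N", "g", "mu", "U", "lambda", "L")) {
  by <- intersect(by, names(df))
  sp <- split(df, df[by], drop = TRUE)
  rows <- lapply(sp, function(d) {
    out <- d[1, by, drop = FALSE]
    out$n_replicates <- nrow(d)
    out$censored_fraction <- mean(d$censored)
    out$extinct_fraction <- mean(d$extinct)
    out$text_mean <- mean(d$text_effective)
    out$text_sd <- sd(d$text_effective)
    out$rate_genome_mean <- mean(d$rate_genome)
    out$rate_genome_sd <- sd(d$rate_genome)
    out$rate_per_locus_mean <- mean(d$rate_per_locus)
    out$rate_per_locus_sd <- sd(d$rate_per_locus)
    out$core_rate_mean <- mean(d$core_rate)
    out$core_rate_sd <- sd(d$core_rate)
    out$accessory_rate_mean <- mean(d$accessory_rate)
    out$accessory_rate_sd <- sd(d$accessory_rate)
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Specify a parameter sweep
#'
#' A sweep is the cross product of genome sizes `g`, recombination lengths
#' `L` (absolute counts or the fraction rule, e.g. `"0.2g"`), and LGT rates
#' `lambda`, sharing the remaining settings. Exactly one of `mu` / `U` is
#' given and is held constant across genome sizes (the per-locus vs
#' genome-wide mutation regimes). Selection is uniform (`s`) or
#' core/accessory (`g_core > 0`).
#'
#' @param g,L,lambda Grid axes (vectors).
#' @param N Population size.
#' @param mu,U One of the two mutation rates.
#' @param s Uniform selection coefficient (ignored when `g_core > 0`).
#' @param form Fitness form, `"linear"` or `"multiplicative"`.
#' @param g_core,s_core,s_accessory Core/accessory regime (see
#'   [fitness_model()]).
#' @param generations Run length (a cap when `stop_at_fixation`).
#' @param replicates Replicates per grid point.
#' @param base_seed Base seed; grid point `k` uses
#'   `base_seed + (k - 1) * replicates` for its replicate batch.
#' @param stop_at_fixation Stop each run at its first fixation (for
#'   extinction-time sweeps).
#' @param event_order,engine Passed to [simulate_run()].
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(g, L, lambda, N, mu = NULL, U = NULL, s = NULL,
                       form = "linear", g_core = 0, s_core = 0.005,
                       s_accessory = 0.001, generations = 10000,
                       replicates = 10, base_seed = 1,
                       stop_at_fixation = FALSE,
                       event_order = "methods", engine = "cpp") {
  if (is.null(mu) == is.null(U)) {
    stop("give exactly one of `mu` (per-locus regime) or `U` (genome-wide regime)",
         call. = FALSE)
  }
  if (g_core == 0 && is.null(s)) {
    stop("uniform selection needs `s`", call. = FALSE)
  }
  structure(
    list(g = as.integer(g), L = L, lambda = lambda, N = as.integer(N),
         mu = mu, U = U,
         mutation_regime = if (is.null(U)) "per_locus" else "genome_wide",
         s = s, form = form, g_core = as.integer(g_core), s_core = s_core,
         s_accessory = s_accessory, generations = as.integer(generations),
         replicates = as.integer(replicates),
         base_seed = as.integer(base_seed),
         stop_at_fixation = isTRUE(stop_at_fixation),
         event_order = event_order, engine = engine),
    class = "sweep_spec"
  )
}

grid_of <- function(spec) {
  grid <- expand.grid(g = spec$g, L_spec = as.character(spec$L),
                      lambda = spec$lambda, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$L <- mapply(function(l, g) tryCatch(resolve_L(l_as_spec(l), g),
                                           error = function(e) NA_integer_),
                   grid$L_spec, grid$g)
  grid
}

# grid L values arrive as strings; turn pure numbers back into numerics
l_as_spec <- function(l) {
  if (grepl("g$", l)) l else as.numeric(l)
}

point_objects <- function(spec, g, L, lambda) {
  params <- sim_params(
    N = spec$N, g = g,
    mu = if (spec$mutation_regime == "per_locus") spec$mu else NULL,
    U = if (spec$mutation_regime == "genome_wide") spec$U else NULL,
    lambda = lambda, L = L, generations = spec$generations)
  fm <- if (spec$g_core > 0) {
    fitness_model(g = g, form = spec$form, g_core = spec$g_core,
                  s_core = spec$s_core, s_accessory = spec$s_accessory)
  } else {
    fitness_model(g = g, s = spec$s, form = spec$form)
  }
  list(params = params, fm = fm)
}

#' Sweep over genome size, recombination length and LGT rate
#'
#' Runs seeded replicate batches over the grid of a [sweep_spec()] and
#' returns the tidy per-replicate table together with the per-grid-point
#' aggregation (mean and SD over replicates). Infeasible grid points
#' (resolved `L > g`) are skipped with a warning. This is the workhorse
#' behind extinction-time-vs-genome-size and fixation-rate-vs-genome-size
#' experiments under either mutation regime.
#'
#' @param spec A [sweep_spec()].
#' @param progress Emit per-point progress messages.
#' @return An object of class `sweep_table`: list with `per_replicate` and
#'   `aggregated` data.frames (both carry `L_spec`, the unresolved length
#'   rule, alongside the resolved `L`).
#' @export
sweep_genome_size <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  grid <- grid_of(spec)
  reps <- list()
  for (k in seq_len(nrow(grid))) {
    g <- grid$g[k]
    L <- grid$L[k]
    if (is.na(L) || L > g) {
      warning(sprintf("skipping infeasible grid point g = %d, L = %s",
                      g, grid$L_spec[k]), call. = FALSE)
      next
    }
    obj <- point_objects(spec, g, L, grid$lambda[k])
    if (progress) {
      message(sprintf("grid point %d/%d: g = %d, L = %d, lambda = %g",
                      k, nrow(grid), g, L, grid$lambda[k]))
    }
    df <- run_replicates(obj$params, obj$fm, spec$replicates,
                         base_seed = spec$base_seed + (k - 1L) * spec$replicates,
                         engine = spec$engine,
                         stop_at_fixation = spec$stop_at_fixation,
                         event_order = spec$event_order)
    df$L_spec <- grid$L_spec[k]
    reps[[length(reps) + 1]] <- df
  }
  per_replicate <- if (length(reps)) do.call(rbind, reps) else
    cbind(run_summary_prototype(), L_spec = character(0))
  aggregated <- if (nrow(per_replicate)) {
    aggregate_replicates(per_replicate,
                         by = c("N", "g", "L_spec", "L", "lambda"))
  } else {
    per_replicate[0, intersect(c("N", "g", "L_spec", "L", "lambda"),
                               names(per_replicate)), drop = FALSE]
  }
  structure(list(per_replicate = per_replicate, aggregated = aggregated,
                 spec = spec),
            class = "sweep_table")
}

run_summary_prototype <- function() {
  p <- sim_params(N = 1, g = 1, mu = 0, generations = 1)
  fm <- fitness_model(g = 1, s = 0)
  run <- simulate_run(p, fm, seed = 0)
  run_summary(run)[0, ]
}

#' Core vs accessory genome experiment
#'
#' Runs the non-uniform selection regime — a fixed-size, strongly selected
#' core genome randomly interleaved with a weakly selected accessory genome
#' — over the grid of a [sweep_spec()] with `g_core > 0`. On top of the
#' sweep tables it returns a per-locus fixation map (fixed mutation levels
#' and first-fixation generation at every locus of every replicate, with
#' the core flag), the analogue of plotting fixed mutations along the
#' genome.
#'
#' @param spec A [sweep_spec()] with `g_core > 0`.
#' @param progress Emit per-point progress messages.
#' @return A `sweep_table` with an extra `fixation_map` data.frame.
#' @export
core_accessory_experiment <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (spec$g_core <= 0) {
    stop("core_accessory_experiment needs a spec with g_core > 0",
         call. = FALSE)
  }
  if (spec$g_core > min(spec$g)) {
    stop("g_core exceeds the smallest genome size in the grid", call. = FALSE)
  }
  grid <- grid_of(spec)
  reps <- list()
  maps <- list()
  for (k in seq_len(nrow(grid))) {
    g <- grid$g[k]
    L <- grid$L[k]
    if (is.na(L) || L > g) {
      warning(sprintf("skipping infeasible grid point g = %d, L = %s",
                      g, grid$L_spec[k]), call. = FALSE)
      next
    }
    obj <- point_objects(spec, g, L, grid$lambda[k])
    if (progress) {
      message(sprintf("grid point %d/%d: g = %d, L = %d, lambda = %g",
                      k, nrow(grid), g, L, grid$lambda[k]))
    }
    res <- run_replicates(obj$params, obj$fm, spec$replicates,
                          base_seed = spec$base_seed + (k - 1L) * spec$replicates,
                          engine = spec$engine,
                          stop_at_fixation = spec$stop_at_fixation,
                          event_order = spec$event_order, detail = TRUE)
    df <- res$summaries
    df$L_spec <- grid$L_spec[k]
    reps[[length(reps) + 1]] <- df
    maps[[length(maps) + 1]] <- do.call(rbind, lapply(seq_along(res$runs),
      function(i) {
        run <- res$runs[[i]]
        data.frame(g = g, L = L, lambda = grid$lambda[k], replicate = i,
                   locus = seq_len(g), is_core = run$fm$core_mask,
                   fixed_count = run$tracker$fixed_mutation_count,
                   first_fixation_generation =
                     run$tracker$first_fixation_generation)
      }))
  }
  per_replicate <- do.call(rbind, reps)
  out <- structure(
    list(per_replicate = per_replicate,
         aggregated = aggregate_replicates(per_replicate,
                                           by = c("N", "g", "L_spec", "L", "lambda")),
         fixation_map = do.call(rbind, maps),
         spec = spec),
    class = "sweep_table")
  out
}

#' @export
print.sweep_table <- function(x, ...) {
  cat(sprintf("Sweep: %d replicate rows over %d grid points\n",
              nrow(x$per_replicate), nrow(x$aggregated)))
  print(x$aggregated, digits = 4)
  invisible(x)
}
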