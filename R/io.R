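#' Load and validate a run configuration
#'
#' Configurations are flat YAML key/value files; command-line flags (or the
#' `overrides` list) take precedence over file values. Unknown keys are
#' rejected, exactly one of `mu` / `U` may be given (the other is derived
#' from `U = mu * g`), and the fully resolved configuration — including the
#' derived mutation rate and, for scalar grids, the resolved recombination
#' length — is what [write_outputs()] echoes to the metadata file, so a run
#' can be reproduced from its own output.
#'
#' Recognised keys: `name`, `N`, `g`, `mu`, `U`, `s`, `form`, `lambda`,
#' `L`, `g_core`, `s_core`, `s_accessory`, `generations`, `replicates`,
#' `base_seed`, `stop_at_fixation`, `event_order`, `engine`, `out_dir`,
#' `force`, `verbose`. `g`, `L` and `lambda` may be vectors, in which case
#' the configuration describes a sweep grid.
#'
#' @param path Path to a YAML file, or `NULL` to configure from `overrides`
#'   alone.
#' @param overrides Named list overriding file values (recorded in the
#'   resolved configuration).
#' @return An object of class `run_config`.
#' @examples
#' cfg <- load_config(overrides = list(N = 100, g = 100, mu = 1e-4, s = 1e-3))
#' cfg$U   # derived: 0.01
#' @export
load_config <- function(path = NULL, overrides = list()) {
  known <- c("name", "N", "g", "mu", "U", "s", "form", "lambda", "L",
             "g_core", "s_core", "s_accessory", "generations", "replicates",
             "base_seed", "stop_at_fixation", "event_order", "engine",
             "out_dir", "force", "verbose")
  defaults <- list(name = "run", lambda = 0, L = 1, form = "linear",
                   g_core = 0, s_core = 0.005, s_accessory = 0.001,
                   generations = 10000, replicates = 1, base_seed = 1,
                   stop_at_fixation = FALSE, event_order = "methods",
                   engine = "cpp", out_dir = ".", force = FALSE,
                   verbose = FALSE)

  file_cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    # keep YAML-1.1 boolean-like scalars (notably the key "N") as strings;
    # logical keys are coerced back below
    keep_string <- function(x) x
    file_cfg <- yaml::read_yaml(path, handlers = list("bool#yes" = keep_string,
                                                      "bool#no" = keep_string))
    if (is.null(file_cfg)) file_cfg <- list()
  }
  for (src in list(file_cfg, overrides)) {
    bad <- setdiff(names(src), known)
    if (length(bad)) {
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  cfg <- modifyList(defaults, file_cfg)
  cfg <- modifyList(cfg, overrides)
  for (k in c("stop_at_fixation", "force", "verbose")) {
    if (is.character(cfg[[k]])) {
      cfg[[k]] <- tolower(cfg[[k]]) %in% c("true", "yes", "y", "on", "1")
    }
  }

  for (key in c("N", "g")) {
    if (is.null(cfg[[key]])) {
      stop("missing required configuration key: ", key, call. = FALSE)
    }
  }
  if (is.null(cfg$mu) && is.null(cfg$U)) {
    stop("one of `mu` or `U` must be configured", call. = FALSE)
  }
  if (!is.null(cfg$mu) && !is.null(cfg$U)) {
    if (length(cfg$g) != 1 || cfg$U != cfg$mu * cfg$g) {
      stop("`mu` and `U` are both given but inconsistent (U must equal mu * g)",
           call. = FALSE)
    }
  }
  if (cfg$g_core == 0 && is.null(cfg$s)) {
    stop("missing required configuration key: s (or a core/accessory regime via g_core)",
         call. = FALSE)
  }

  cfg$mutation_regime <- if (is.null(cfg$U)) "per_locus" else "genome_wide"
  cfg$is_sweep <- length(cfg$g) > 1 || length(cfg$L) > 1 || length(cfg$lambda) > 1
  if (!cfg$is_sweep) {
    # single point: resolve everything now and validate via the constructors
    obj <- config_objects(cfg)
    cfg$L_resolved <- obj$params$L
    cfg$mu <- obj$params$mu
    cfg$U <- obj$params$U
  }
  cfg$overrides_applied <- names(overrides)
  structure(cfg, class = "run_config")
}

#' Build simulation objects from a configuration
#'
#' A single-point configuration yields its [sim_params()] / [fitness_model()]
#' pair; a grid configuration yields the corresponding [sweep_spec()].
#'
#' @param cfg A [load_config()] result.
#' @return A list with `params` and `fm`, or a list with `spec`.
#' @export
config_objects <- function(cfg) {
  if (isTRUE(cfg$is_sweep)) {
    return(list(spec = sweep_spec(
      g = cfg$g, L = cfg$L, lambda = cfg$lambda, N = cfg$N,
      mu = if (cfg$mutation_regime == "per_locus") cfg$mu else NULL,
      U = if (cfg$mutation_regime == "genome_wide") cfg$U else NULL,
      s = cfg$s, form = cfg$form, g_core = cfg$g_core, s_core = cfg$s_core,
      s_accessory = cfg$s_accessory, generations = cfg$generations,
      replicates = cfg$replicates, base_seed = cfg$base_seed,
      stop_at_fixation = cfg$stop_at_fixation,
      event_order = cfg$event_order, engine = cfg$engine)))
  }
  params <- sim_params(N = cfg$N, g = cfg$g,
                       mu = if (cfg$mutation_regime == "per_locus") cfg$mu else NULL,
                       U = if (cfg$mutation_regime == "genome_wide") cfg$U else NULL,
                       lambda = cfg$lambda, L = cfg$L,
                       generations = cfg$generations)
  fm <- if (cfg$g_core > 0) {
    fitness_model(g = cfg$g, form = cfg$form, g_core = cfg$g_core,
                  s_core = cfg$s_core, s_accessory = cfg$s_accessory)
  } else {
    fitness_model(g = cfg$g, s = cfg$s, form = cfg$form)
  }
  list(params = params, fm = fm)
}

#' Write experiment tables and metadata to disk
#'
#' Writes the per-replicate table, the aggregated table, the per-locus
#' fixation map when present, and a JSON metadata file carrying the
#' resolved configuration echo, the seeds used, and the package version.
#' File names are deterministic from the experiment name; tables are plain
#' RFC-4180 CSV with a header row, so two runs with the same configuration
#' and seed produce byte-identical tables. Existing files are never
#' silently overwritten: set `force = TRUE` to replace them. The
#' destination is checked before anything is written (fail fast).
#'
#' @param tables A `sweep_table`, or any list with data.frame elements
#'   `per_replicate` / `aggregated` (and optionally `fixation_map`).
#' @param config The [run_config][load_config()] (or any list) echoed into
#'   the metadata.
#' @param destination Output directory (created if absent).
#' @param name Experiment name prefixing the files; defaults to
#'   `config$name`.
#' @param force Overwrite existing files.
#' @return (Invisibly) the paths written.
#' @export
write_outputs <- function(tables, config, destination, name = NULL,
                          force = FALSE) {
  if (is.null(name)) name <- if (!is.null(config$name)) config$name else "run"
  if (!dir.exists(destination)) {
    ok <- dir.create(destination, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", destination, call. = FALSE)
  }
  if (file.access(destination, mode = 2) != 0) {
    stop("output directory not writable: ", destination, call. = FALSE)
  }

  dfs <- list(replicates = tables$per_replicate,
              summary = tables$aggregated)
  if (!is.null(tables$fixation_map)) dfs$fixation_map <- tables$fixation_map
  paths <- file.path(destination, paste0(name, "_", names(dfs), ".csv"))
  meta_path <- file.path(destination, paste0(name, "_metadata.json"))
  existing <- c(paths, meta_path)[file.exists(c(paths, meta_path))]
  if (length(existing) && !force) {
    stop("output exists (use force = TRUE to overwrite): ",
         paste(existing, collapse = ", "), call. = FALSE)
  }

  for (i in seq_along(dfs)) {
    write.csv(dfs[[i]], paths[i], row.names = FALSE, quote = TRUE, na = "NA")
  }
  meta <- list(
    config = unclass_config(config),
    package_version = as.character(utils::packageVersion("lgtratchet")),
    written = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = basename(paths))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(c(paths, meta_path))
}

unclass_config <- function(config) {
  cfg <- unclass(config)
  cfg[!vapply(cfg, is.function, logical(1))]
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration", if (isTRUE(x$is_sweep)) "(sweep grid)" else "", "\n")
  keys <- setdiff(names(x), c("is_sweep", "overrides_applied"))
  for (k in keys) {
    v <- x[[k]]
    if (!is.null(v)) cat(sprintf("  %-16s %s\n", k, paste(v, collapse = ", ")))
  }
  if (length(x$overrides_applied)) {
    cat("  overridden keys:", paste(x$overrides_applied, collapse = ", "), "\n")
  }
  invisible(x)
}
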