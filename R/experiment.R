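#' Preset experiment configurations
#'
#' `"calvin-10s"`: the Calvin-Benson model over 10 s, 5 finite elements
#' with fifth-order Legendre roots, on/off tolerances gamma_x = 0.4,
#' gamma_v = 0.2, eps_x = 0.01, eps_v = 0.05, and a +/- 0.1 mmol l-1
#' envelope on GAP taken from the kinetic reference.
#' `"carbohydrate-24h"`: the diurnal carbohydrate model over 24 h, 12
#' two-hour elements with fifth-order roots (wild type or `inv4`
#' invertase knockout).
#'
#' @param name Preset name.
#' @param genotype Genotype for the carbohydrate preset.
#' @return An [experiment_config()].
#' @export
preset <- function(name = c("calvin-10s", "carbohydrate-24h"),
                   genotype = c("wild", "inv4")) {
  name <- tryCatch(match.arg(name),
                   error = function(e)
                     dynfba_abort(sprintf("unknown preset '%s'", name[1]),
                                  class = "dynfba_config_error"))
  genotype <- match.arg(genotype)
  if (name == "calvin-10s") {
    experiment_config(
      model = "calvin", methods = "all",
      t0 = 0, tf = 10, elements = 5, order = 5,
      gamma_x = 0.4, gamma_v = 0.2, eps_x = 0.01, eps_v = 0.05,
      envelope_metabolite = "GAP", envelope_tol = 0.1,
      sink = "Sink", seed = 1, multistart = 1)
  } else {
    experiment_config(
      model = "carbohydrate", genotype = genotype, methods = "all",
      t0 = 0, tf = 24, elements = 12, order = 5,
      gamma_x = 0.4, gamma_v = 0.2, eps_x = 0.01, eps_v = 0.05,
      sink = "Sink", seed = 1, multistart = 1)
  }
}

#' Experiment configuration
#'
#' Validated bundle of everything a reproducible run needs: the model
#' source, the method set, the collocation grid, the on/off tolerances,
#' an optional reference envelope, the seed and the multistart count.
#'
#' @param model `"calvin"`, `"carbohydrate"`, or a path to a native
#'   model file.
#' @param methods `"all"` or a subset of [dfba_methods()].
#' @param t0,tf,elements,order Collocation grid settings.
#' @param gamma_x,gamma_v,eps_x,eps_v On/off significance tolerances for
#'   the binary (MINLP) variants; the relaxed variants always run with
#'   zeros.
#' @param envelope_metabolite,envelope_tol Optional metabolite id and
#'   absolute tolerance for a reference-following concentration envelope.
#' @param reference_csv Optional path to an imported reference
#'   trajectory (long CSV as written by [write_reference_csv()]);
#'   otherwise the built-in kinetic stand-in is simulated.
#' @param genotype Carbohydrate genotype.
#' @param sink Sink metabolite id for classical DFBA.
#' @param seed Non-negative integer seed.
#' @param multistart Restarts for nonconvex solves.
#' @param alpha Weighting of concentration vs flux indicators in the
#'   combined on/off objectives.
#' @param oracle_K Half-saturation constant of the kinetic stand-in.
#' @param options A [solver_options()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(model, methods = "all",
                              t0 = 0, tf = 10, elements = 5, order = 5,
                              gamma_x = 0.4, gamma_v = 0.2,
                              eps_x = 0.01, eps_v = 0.05,
                              envelope_metabolite = NULL,
                              envelope_tol = 0.1,
                              reference_csv = NULL,
                              genotype = "wild", sink = "Sink",
                              seed = 1, multistart = 1, alpha = 0.5,
                              oracle_K = 1,
                              options = solver_options()) {
  if (identical(methods, "all")) methods <- dfba_methods()
  bad <- setdiff(methods, dfba_methods())
  if (length(bad)) {
    dynfba_abort(sprintf("unknown method tag(s): %s",
                         paste(bad, collapse = ", ")),
                 class = "dynfba_config_error")
  }
  if (length(seed) != 1 || is.na(seed) || seed < 0 ||
      seed != round(seed)) {
    dynfba_abort("seed must be a non-negative integer",
                 class = "dynfba_config_error")
  }
  th <- threshold_params(gamma_x, gamma_v, eps_x, eps_v)
  cfg <- structure(
    list(model = model, methods = methods, t0 = t0, tf = tf,
         elements = elements, order = order, thresholds = th,
         envelope_metabolite = envelope_metabolite,
         envelope_tol = envelope_tol, reference_csv = reference_csv,
         genotype = genotype, sink = sink, seed = as.integer(seed),
         multistart = multistart, alpha = alpha, oracle_K = oracle_K,
         options = options),
    class = "experiment_config")
  # fail fast on an invalid grid before any solve
  invisible(collocation_grid(t0, tf, elements, order))
  cfg
}

config_model <- function(cfg) {
  if (identical(cfg$model, "calvin")) return(calvin_model())
  if (identical(cfg$model, "carbohydrate")) {
    return(carbohydrate_model(cfg$genotype))
  }
  read_model(cfg$model)
}

#' Serialize / load an experiment configuration
#'
#' The YAML form embeds every resolved field so a run directory can be
#' reproduced from its own copy of the configuration.
#'
#' @param cfg An [experiment_config()].
#' @param path YAML file path.
#' @return `path` (write) / the configuration (read).
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  lst <- list(
    model = cfg$model, methods = cfg$methods,
    t0 = cfg$t0, tf = cfg$tf, elements = cfg$elements,
    order = cfg$order,
    gamma_x = cfg$thresholds$gamma_x, gamma_v = cfg$thresholds$gamma_v,
    eps_x = cfg$thresholds$eps_x, eps_v = cfg$thresholds$eps_v,
    envelope_metabolite = cfg$envelope_metabolite,
    envelope_tol = cfg$envelope_tol,
    reference_csv = cfg$reference_csv,
    genotype = cfg$genotype, sink = cfg$sink, seed = cfg$seed,
    multistart = cfg$multistart, alpha = cfg$alpha,
    oracle_K = cfg$oracle_K)
  yaml::write_yaml(lst[!vapply(lst, is.null, logical(1))], path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(experiment_config, lst)
}

#' Run a full experiment
#'
#' Builds the model and grid, obtains the reference trajectory
#' (simulating the kinetic stand-in unless an imported reference is
#' configured), applies the optional envelope, builds and solves every
#' configured method, and writes per-method trajectory CSVs, the
#' comparison report, a log and the resolved configuration to the
#' output directory.  Outputs are deterministic given the configuration.
#'
#' @param cfg An [experiment_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with `trajectories`, `reference`,
#'   `comparison`.
#' @export
run_experiment <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = logf, append = TRUE)
  cat(sprintf("dynfba run (R %s, dynfba %s)\n",
              getRversion(),
              as.character(utils::packageVersion("dynfba"))),
      file = logf)
  model <- config_model(cfg)
  grid <- collocation_grid(cfg$t0, cfg$tf, cfg$elements, cfg$order)
  if (!is.null(cfg$reference_csv)) {
    ref <- read_reference_csv(cfg$reference_csv, model)
  } else {
    ref <- simulate_kinetic(kinetic_model(model, K = cfg$oracle_K),
                            cfg$t0, cfg$tf)
  }
  logline("reference: %s", ref$provenance)
  x_lower <- NULL; x_upper <- NULL
  if (!is.null(cfg$envelope_metabolite)) {
    eb <- envelope_bounds(model, grid, ref, cfg$envelope_metabolite,
                          cfg$envelope_tol)
    x_lower <- eb$x_lower; x_upper <- eb$x_upper
    logline("envelope: %s +/- %g", cfg$envelope_metabolite,
            cfg$envelope_tol)
  }
  trajectories <- list()
  for (mth in cfg$methods) {
    prog <- build_method(mth, model, grid, thresholds = cfg$thresholds,
                         alpha = cfg$alpha, sink = cfg$sink,
                         x_lower = x_lower, x_upper = x_upper)
    tr <- solve_dfba(prog, seed = cfg$seed,
                     multistart = cfg$multistart,
                     options = cfg$options)
    trajectories[[mth]] <- tr
    logline("method %s: status %s, objective %.8g, dyn %.2e, bnd %.2e",
            mth, tr$status, tr$objective,
            tr$residuals$dynamics %||% NA,
            tr$residuals$bounds %||% NA)
    readr::write_csv(tidy(tr),
                     file.path(out_dir, paste0("trajectory_", mth,
                                               ".csv")))
  }
  refsamp <- sample_states(ref, grid)
  cmp <- compare_methods(trajectories, refsamp)
  write_comparison(cmp, out_dir)
  readr::write_csv(tidy(refsamp), file.path(out_dir, "reference.csv"))
  write_config(cfg, file.path(out_dir, "config.yaml"))
  logline("done: %d methods", length(trajectories))
  invisible(list(trajectories = trajectories, reference = ref,
                 comparison = cmp))
}
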