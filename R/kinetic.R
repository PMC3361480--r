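#' Saturable-kinetics reference model (synthetic comparison standard)
#'
#' Equips a stoichiometric model with simple saturable rate laws so it
#' can be integrated as an ODE system and used as the reference that the
#' constraint-based predictions are evaluated against.  Each reaction
#' runs at
#' \deqn{v_l(x, t) = v_{max,l}(t) \prod_{s} \frac{x_s}{K_l + x_s}}
#' over its consumed metabolites \eqn{s} (reactions without substrates
#' run at \eqn{v_{max,l}(t)}).  This is an explicitly synthetic stand-in:
#' the rate laws behind the published reference trajectories are not
#' publicly available, so all evaluation against this oracle is labelled
#' as such in reports.
#'
#' @param model A [stoich_model()].
#' @param K Half-saturation constant(s), mmol l-1; a scalar recycled over
#'   reactions or a vector named by reaction id.  Must be positive.
#' @return An object of class `kinetic_model`.
#' @export
kinetic_model <- function(model, K = 1) {
  stopifnot(inherits(model, "stoich_model"))
  if (is.null(names(K))) {
    K <- stats::setNames(rep_len(K, model$F), model$reactions$id)
  } else {
    full <- stats::setNames(rep(1, model$F), model$reactions$id)
    full[names(K)] <- K
    K <- full
  }
  if (any(K <= 0)) {
    dynfba_abort("half-saturation constants must be positive",
                 class = "dynfba_model_error")
  }
  structure(list(model = model, K = K, S = stoich_matrix(model)),
            class = "kinetic_model")
}

# instantaneous flux vector at state x, time t
kinetic_rates <- function(km, x, t) {
  model <- km$model
  v <- numeric(model$F)
  xs <- pmax(x, 0)
  for (k in seq_len(model$F)) {
    cap <- bound_at(reaction_bound(model$reactions$v_max, k), t)
    st <- model$reactions$stoich[[k]]
    subs <- names(st)[st < 0]
    sat <- 1
    for (s in subs) sat <- sat * xs[[s]] / (km$K[[k]] + xs[[s]])
    v[k] <- cap * sat
  }
  v
}

#' Integrate the kinetic reference model
#'
#' Stiff-capable integration (deSolve, lsoda) of
#' \eqn{dX/dt = S \, v(x, t)} on a dense output grid, storing both the
#' concentrations and the instantaneous fluxes.
#'
#' @param km A [kinetic_model()].
#' @param t0,tf Horizon.
#' @param x0 Optional initial concentrations (defaults to the model's).
#' @param rtol,atol Integration tolerances.
#' @param n_out Number of dense output times (the collocation nodes used
#'   later are interpolated from this grid by cubic splines).
#' @return An object of class `reference_trajectory` with fields `times`,
#'   `conc` (N x n), `flux` (F x n), `model` and `provenance`.
#' @export
simulate_kinetic <- function(km, t0, tf, x0 = NULL,
                             rtol = 1e-8, atol = 1e-10, n_out = 401) {
  stopifnot(inherits(km, "kinetic_model"), tf > t0)
  model <- km$model
  x0 <- x0 %||% stats::setNames(model$metabolites$x0, model$metabolites$id)
  if (any(x0 < 0)) {
    dynfba_abort("initial concentrations must be non-negative",
                 class = "dynfba_model_error")
  }
  S <- km$S
  deriv <- function(t, x, p) list(as.vector(S %*% kinetic_rates(km, x, t)))
  times <- seq(t0, tf, length.out = n_out)
  sol <- deSolve::ode(y = x0, times = times, func = deriv, parms = NULL,
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    dynfba_abort("kinetic integration failed", class = "dynfba_solver_error")
  }
  conc <- t(unclass(sol)[, -1, drop = FALSE])
  if (min(conc) < -sqrt(atol)) {
    dynfba_abort("kinetic integration produced negative concentrations",
                 class = "dynfba_solver_error")
  }
  conc <- pmax(conc, 0)
  flux <- matrix(0, model$F, length(times))
  for (j in seq_along(times)) {
    flux[, j] <- kinetic_rates(km, conc[, j], times[j])
  }
  rownames(conc) <- model$metabolites$id
  rownames(flux) <- model$reactions$id
  structure(list(times = times, conc = conc, flux = flux,
                 model = model, provenance = "synthetic kinetic stand-in"),
            class = "reference_trajectory")
}

#' @export
print.reference_trajectory <- function(x, ...) {
  cat(sprintf("<reference_trajectory> %s, t in [%g, %g], %d stored times\n",
              x$provenance, min(x$times), max(x$times), length(x$times)))
  invisible(x)
}

#' Evaluate a reference trajectory at arbitrary times
#'
#' @param ref A [simulate_kinetic()] result.
#' @param t Query times within the stored horizon.
#' @return List with `conc` (N x length(t)) and `flux` (F x length(t)).
#' @export
reference_at <- function(ref, t) {
  stopifnot(inherits(ref, "reference_trajectory"))
  if (any(t < min(ref$times) - 1e-9) || any(t > max(ref$times) + 1e-9)) {
    dynfba_abort("query time outside the stored horizon",
                 class = "dynfba_grid_error")
  }
  interp_mat <- function(Mx) {
    out <- matrix(0, nrow(Mx), length(t), dimnames = list(rownames(Mx)))
    hit <- match(t, ref$times)
    for (i in seq_len(nrow(Mx))) {
      v <- stats::spline(ref$times, Mx[i, ], xout = t)$y
      # exact reproduction at stored times
      v[!is.na(hit)] <- Mx[i, hit[!is.na(hit)]]
      out[i, ] <- v
    }
    out
  }
  list(conc = interp_mat(ref$conc), flux = interp_mat(ref$flux))
}

#' Bound envelope around a reference metabolite trajectory
#'
#' Lower/upper concentration bounds following the reference with an added
#' absolute tolerance, clipped below at zero:
#' lower = max(0, ref(t) - tol), upper = ref(t) + tol.
#'
#' @param ref A [simulate_kinetic()] result.
#' @param metabolite Metabolite id.
#' @param times Times at which the envelope is needed (collocation nodes).
#' @param tol Absolute tolerance, mmol l-1 (e.g. 0.1).
#' @return Tibble with columns `time`, `lower`, `upper`.
#' @export
envelope <- function(ref, metabolite, times, tol) {
  stopifnot(inherits(ref, "reference_trajectory"), tol >= 0)
  if (!metabolite %in% rownames(ref$conc)) {
    dynfba_abort(sprintf("unknown metabolite '%s'", metabolite),
                 class = "dynfba_model_error")
  }
  v <- reference_at(ref, times)$conc[metabolite, ]
  tibble::tibble(time = times, lower = pmax(0, v - tol), upper = v + tol)
}

#' Node-resolved concentration bounds with a reference envelope applied
#'
#' Starts from the model's constant concentration box and replaces the
#' rows of `metabolite` with the reference-following envelope
#' (see [envelope()]), ready to pass as `x_lower`/`x_upper` to the
#' program builders.
#'
#' @param model A [stoich_model()].
#' @param grid A [collocation_grid()].
#' @param ref A [simulate_kinetic()] result (or imported reference).
#' @param metabolite Metabolite id to constrain.
#' @param tol Absolute envelope tolerance.
#' @return List with `x_lower` and `x_upper` (N x M matrices).
#' @export
envelope_bounds <- function(model, grid, ref, metabolite, tol) {
  cb <- conc_bounds_at(model, grid$M)
  env <- envelope(ref, metabolite, grid$node_times, tol)
  i <- match(metabolite, model$metabolites$id)
  cb$lower[i, ] <- env$lower
  cb$upper[i, ] <- env$upper
  list(x_lower = cb$lower, x_upper = cb$upper)
}

#' Sample a reference trajectory at collocation nodes
#'
#' Returns the reference in the same shape as a solver trajectory so the
#' evaluation functions can compare them node by node.
#'
#' @param ref A [simulate_kinetic()] result.
#' @param grid A [collocation_grid()] (or a numeric vector of times).
#' @return A `dfba_trajectory` with method tag `"kinetic_reference"`.
#' @export
sample_states <- function(ref, grid) {
  times <- if (inherits(grid, "collocation_grid")) grid$node_times else grid
  at <- reference_at(ref, times)
  x0 <- ref$conc[, 1]
  starts <- NULL
  if (inherits(grid, "collocation_grid")) {
    starts <- reference_at(ref, grid$element_bounds[seq_len(grid$E)])$conc
  }
  new_trajectory(
    method = "kinetic_reference",
    grid = if (inherits(grid, "collocation_grid")) grid else NULL,
    times = times, x0 = x0, conc = at$conc, flux = at$flux,
    starts = starts, objective = NA_real_, status = "reference",
    residuals = NULL, provenance = ref$provenance)
}

#' Export / import a reference trajectory as long-format CSV
#'
#' Columns: `time`, `kind` (`conc` or `flux`), `id`, `value`.  An
#' externally computed kinetic trajectory in this format can replace the
#' built-in stand-in for evaluation.
#'
#' @param ref A [simulate_kinetic()] result.
#' @param path CSV path.
#' @return `path` (write) or a `reference_trajectory` (read).
#' @export
write_reference_csv <- function(ref, path) {
  stopifnot(inherits(ref, "reference_trajectory"))
  long <- dplyr::bind_rows(
    mat_to_long(ref$conc, ref$times, "conc"),
    mat_to_long(ref$flux, ref$times, "flux"))
  readr::write_csv(long, path)
  invisible(path)
}

#' @rdname write_reference_csv
#' @param model The [stoich_model()] the trajectory belongs to.
#' @export
read_reference_csv <- function(path, model) {
  long <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time", "kind", "id", "value")
  if (!all(need %in% names(long))) {
    dynfba_abort("reference CSV needs columns time, kind, id, value",
                 class = "dynfba_parse_error")
  }
  times <- sort(unique(long$time))
  pick <- function(kind, ids) {
    sub <- long[long$kind == kind, ]
    out <- matrix(NA_real_, length(ids), length(times),
                  dimnames = list(ids, NULL))
    for (id in ids) {
      rows <- sub[sub$id == id, ]
      out[id, ] <- rows$value[match(times, rows$time)]
    }
    if (anyNA(out)) {
      dynfba_abort("reference CSV is not a complete time grid",
                   class = "dynfba_parse_error")
    }
    out
  }
  structure(list(times = times,
                 conc = pick("conc", model$metabolites$id),
                 flux = pick("flux", model$reactions$id),
                 model = model, provenance = sprintf("imported (%s)", path)),
            class = "reference_trajectory")
}

mat_to_long <- function(Mx, times, kind) {
  tibble::tibble(
    time = rep(times, each = nrow(Mx)),
    kind = kind,
    id = rep(rownames(Mx), length(times)),
    value = as.vector(Mx))
}
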