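#' Significance thresholds for the on/off (R-DFBA) programs
#'
#' Relative (`gamma`) and absolute (`eps`) tolerance ranges defining the
#' band around the previous node's value inside which a change does not
#' count as significant: the upper/lower concentration thresholds at node
#' j are \eqn{w^u = x_{j-1} + \gamma_x x_{j-1} + \epsilon_x} and
#' \eqn{w^l = x_{j-1} - \gamma_x x_{j-1} - \epsilon_x}, and analogously
#' \eqn{b^u, b^l} for fluxes with \eqn{\gamma_v, \epsilon_v}.  Defaults
#' are the values used for the Calvin-Benson comparison.
#'
#' @param gamma_x,gamma_v Relative tolerances (dimensionless, >= 0).
#' @param eps_x,eps_v Absolute tolerances (concentration / flux units).
#' @return An object of class `threshold_params`.
#' @export
threshold_params <- function(gamma_x = 0.4, gamma_v = 0.2,
                             eps_x = 0.01, eps_v = 0.05) {
  vals <- c(gamma_x = gamma_x, gamma_v = gamma_v,
            eps_x = eps_x, eps_v = eps_v)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    dynfba_abort("threshold tolerances must be finite and >= 0",
                 class = "dynfba_program_error")
  }
  structure(as.list(vals), class = "threshold_params")
}

#' The ten dynamic constraint-based method tags
#'
#' @return Character vector of the method vocabulary understood by
#'   [build_method()] and the experiment driver: classical DFBA, the
#'   three smooth minimal-fluctuation variants (concentration, flux,
#'   combined), and the six on/off variants (concentration, flux,
#'   combined; each as a relaxed NLP or a binary MINLP).
#' @export
dfba_methods <- function() {
  c("dfba",
    "mdfba", "mdfba_flux", "mdfba_cf",
    "rdfba_nlp", "rdfba_flux_nlp", "rdfba_cf_nlp",
    "rdfba_minlp", "rdfba_flux_minlp", "rdfba_cf_minlp")
}

# shared skeleton for all program builders
new_program <- function(model, grid, method, mode = NULL, relaxed = FALSE,
                        thresholds = NULL, alpha = 0.5, sink = NULL,
                        x_lower = NULL, x_upper = NULL) {
  stopifnot(inherits(model, "stoich_model"),
            inherits(grid, "collocation_grid"))
  cb <- conc_bounds_at(model, grid$M)
  if (!is.null(x_lower)) cb$lower <- check_bound_mat(x_lower, model, grid)
  if (!is.null(x_upper)) cb$upper <- check_bound_mat(x_upper, model, grid)
  if (any(cb$lower > cb$upper + 1e-12)) {
    dynfba_abort("concentration lower bound exceeds upper bound",
                 class = "dynfba_program_error")
  }
  vb <- flux_bounds_at(model, grid$node_times)
  structure(
    list(method = method, model = model, grid = grid, mode = mode,
         relaxed = relaxed, thresholds = thresholds, alpha = alpha,
         sink = sink,
         x_lower = cb$lower, x_upper = cb$upper,
         v_lower = vb$lower, v_upper = vb$upper,
         has_y = grepl("^rdfba", method) && !grepl("flux", method),
         has_z = grepl("^rdfba", method) && grepl("flux|cf", method),
         binary = grepl("minlp$", method)),
    class = "dfba_program")
}

check_bound_mat <- function(B, model, grid) {
  B <- rbind(B)
  if (nrow(B) != model$N || ncol(B) != grid$M) {
    dynfba_abort("node bound matrices must be N x M",
                 class = "dynfba_program_error")
  }
  rownames(B) <- model$metabolites$id
  B
}

#' Classical dynamic FBA program (dynamic optimization approach)
#'
#' Maximizes the integral of the sink concentration over the horizon
#' (Gauss-quadrature of the collocation polynomial), subject to the
#' collocated dynamics \eqn{dX/dt = S v}, continuity across elements,
#' the initial condition, and box bounds on fluxes and concentrations.
#'
#' @param model A [stoich_model()].
#' @param grid A [collocation_grid()].
#' @param sink Metabolite id whose production is the systemic objective.
#' @param x_lower,x_upper Optional N x M node-resolved concentration
#'   bounds (e.g. a reference envelope from [envelope()]), overriding the
#'   model's constant bounds.
#' @return A `dfba_program` (method `"dfba"`); solve with [solve_dfba()].
#' @export
build_dfba <- function(model, grid, sink = "Sink",
                       x_lower = NULL, x_upper = NULL) {
  if (!sink %in% model$metabolites$id) {
    dynfba_abort(sprintf("unknown metabolite id '%s'", sink),
                 class = "dynfba_program_error")
  }
  new_program(model, grid, "dfba", sink = sink,
              x_lower = x_lower, x_upper = x_upper)
}

#' Minimal-fluctuation (MOMA-style) dynamic FBA programs
#'
#' Minimizes the summed squared changes between adjacent collocation
#' nodes in the single global time ordering: concentrations
#' (\eqn{\sum_j \sum_i (x_{i,j} - x_{i,j-1})^2}, with the j = 1 term
#' against the initial condition), fluxes
#' (\eqn{\sum_j \sum_l (v_{l,j} - v_{l,j-1})^2}, starting at the second
#' node since fluxes carry no initial value), or their sum (`"both"`).
#'
#' @inheritParams build_dfba
#' @param mode `"conc"`, `"flux"` or `"both"`.
#' @return A `dfba_program` (methods `mdfba`, `mdfba_flux`, `mdfba_cf`).
#' @export
build_mdfba <- function(model, grid, mode = c("conc", "flux", "both"),
                        x_lower = NULL, x_upper = NULL) {
  mode <- match.arg(mode)
  method <- switch(mode, conc = "mdfba", flux = "mdfba_flux",
                   both = "mdfba_cf")
  new_program(model, grid, method, mode = mode,
              x_lower = x_lower, x_upper = x_upper)
}

#' On/off minimization (ROOM-style) dynamic FBA programs
#'
#' Minimizes the number of significant changes between adjacent
#' collocation nodes, encoded with indicator variables \eqn{y_{i,j}}
#' (concentrations) and/or \eqn{z_{l,j}} (fluxes) and big-M threshold
#' constraints around the previous node's value:
#' \deqn{x_{i,j} - y_{i,j}(x_{max,i,j} - w^u_{i,j}) \le w^u_{i,j}, \quad
#'       x_{i,j} - y_{i,j}(x_{min,i,j} - w^l_{i,j}) \ge w^l_{i,j}}
#' with thresholds from [threshold_params()], clipped into the node's
#' concentration box so that an indicator of 1 is always feasible.  Flux
#' constraints are analogous with \eqn{b^u, b^l} and start at the second
#' node.  With `relaxed = TRUE` the indicators become box-[0,1]
#' variables and all four tolerances are forced to zero (the NLP
#' relaxation); otherwise the indicators are binary and the program is a
#' MINLP solved by branch and bound.
#'
#' @inheritParams build_mdfba
#' @param relaxed Relax binary indicators to [0, 1]?
#' @param thresholds A [threshold_params()]; must be all-zero when
#'   `relaxed = TRUE` (the default then).
#' @param alpha Weight of the concentration indicators in the combined
#'   (`"both"`) objective, \eqn{\sum \alpha y + \sum (1-\alpha) z} scaled
#'   by 2 so the default 0.5 reproduces the unweighted sum.
#' @return A `dfba_program` (six methods depending on `mode`/`relaxed`).
#' @export
build_rdfba <- function(model, grid, mode = c("conc", "flux", "both"),
                        relaxed = FALSE, thresholds = NULL, alpha = 0.5,
                        x_lower = NULL, x_upper = NULL) {
  mode <- match.arg(mode)
  if (relaxed) {
    if (is.null(thresholds)) thresholds <- threshold_params(0, 0, 0, 0)
    nz <- unlist(thresholds)
    if (any(nz != 0)) {
      dynfba_abort(
        "relaxed R-DFBA requires zero tolerances (gamma = eps = 0)",
        class = "dynfba_program_error")
    }
  } else if (is.null(thresholds)) {
    thresholds <- threshold_params()
  }
  stopifnot(inherits(thresholds, "threshold_params"),
            alpha >= 0, alpha <= 1)
  method <- paste0("rdfba",
                   switch(mode, conc = "", flux = "_flux", both = "_cf"),
                   if (relaxed) "_nlp" else "_minlp")
  new_program(model, grid, method, mode = mode, relaxed = relaxed,
              thresholds = thresholds, alpha = alpha,
              x_lower = x_lower, x_upper = x_upper)
}

#' Build any of the ten programs by method tag
#'
#' @param method One of [dfba_methods()].
#' @inheritParams build_rdfba
#' @param sink Sink metabolite id (classical DFBA only).
#' @return A `dfba_program`.
#' @export
build_method <- function(method, model, grid, thresholds = NULL,
                         alpha = 0.5, sink = "Sink",
                         x_lower = NULL, x_upper = NULL) {
  method <- match.arg(method, dfba_methods())
  if (method == "dfba") {
    return(build_dfba(model, grid, sink = sink,
                      x_lower = x_lower, x_upper = x_upper))
  }
  if (grepl("^mdfba", method)) {
    mode <- switch(method, mdfba = "conc", mdfba_flux = "flux",
                   mdfba_cf = "both")
    return(build_mdfba(model, grid, mode, x_lower, x_upper))
  }
  mode <- if (grepl("cf", method)) "both"
          else if (grepl("flux", method)) "flux" else "conc"
  relaxed <- grepl("nlp$", method)
  build_rdfba(model, grid, mode, relaxed = relaxed,
              thresholds = if (relaxed) NULL else
                (thresholds %||% threshold_params()),
              alpha = alpha, x_lower = x_lower, x_upper = x_upper)
}

#' @export
print.dfba_program <- function(x, ...) {
  g <- x$grid
  cat(sprintf("<dfba_program> method '%s' on %d metabolites x %d reactions\n",
              x$method, x$model$N, x$model$F))
  cat(sprintf(" grid: [%g, %g], E=%d, order=%d (M=%d nodes)\n",
              g$t0, g$tf, g$E, g$order, g$M))
  d <- program_dims(x)
  cat(sprintf(" variables: %d conc + %d flux", d$n_conc, d$n_flux))
  if (d$n_indicator > 0) {
    cat(sprintf(" + %d %s indicators", d$n_indicator,
                if (x$binary) "binary" else "box-[0,1]"))
  }
  cat("\n")
  obj <- switch(x$method,
    dfba = sprintf("maximize integral of %s concentration", x$sink),
    mdfba = "minimize sum of squared concentration changes",
    mdfba_flux = "minimize sum of squared flux changes",
    mdfba_cf = "minimize sum of squared concentration + flux changes",
    sprintf("minimize count of significant %s changes (%s)",
            switch(x$mode, conc = "concentration", flux = "flux",
                   both = "concentration + flux"),
            if (x$relaxed) "relaxed NLP" else "MINLP"))
  cat(" objective:", obj, "\n")
  if (!is.null(x$thresholds)) {
    cat(sprintf(" thresholds: gamma_x=%g gamma_v=%g eps_x=%g eps_v=%g\n",
                x$thresholds$gamma_x, x$thresholds$gamma_v,
                x$thresholds$eps_x, x$thresholds$eps_v))
  }
  invisible(x)
}

#' Decision-variable bookkeeping of a program
#'
#' @param program A `dfba_program`.
#' @return One-row tibble: node concentration variables, element-start
#'   variables, flux variables, indicator variables.
#' @export
program_dims <- function(program) {
  g <- program$grid; m <- program$model
  tibble::tibble(
    n_conc = m$N * g$M,
    n_start = m$N * (g$E - 1),
    n_flux = m$F * g$M,
    n_indicator = (if (program$has_y) m$N * g$M else 0) +
      (if (program$has_z) m$F * (g$M - 1) else 0),
    n_node_total = (m$N + m$F) * g$M
  )
}

#' Evaluate a program's stated objective at a candidate point
#'
#' Computes the objective exactly as written in the program definition,
#' independent of any solver: quadrature of the sink for DFBA, sums of
#' squared adjacent-node differences for the M-DFBA family (the first
#' concentration difference is taken against the initial condition; flux
#' differences start at the second node), and the (weighted) indicator
#' counts for the R-DFBA family.
#'
#' @param program A `dfba_program`.
#' @param conc N x M concentrations at the nodes (rows in model order).
#' @param flux F x M fluxes at the nodes.
#' @param y,z Optional indicator matrices (N x M and F x (M-1)) for the
#'   R-DFBA programs.
#' @param x0 Initial concentrations; defaults to the model's.
#' @return The objective value (a single number).
#' @export
objective_value <- function(program, conc, flux = NULL, y = NULL, z = NULL,
                            x0 = NULL) {
  stopifnot(inherits(program, "dfba_program"))
  m <- program$model; g <- program$grid
  x0 <- x0 %||% m$metabolites$x0
  conc <- rbind(conc)
  if (program$method == "dfba") {
    ops <- integration_operator(g)
    i <- match(program$sink, m$metabolites$id)
    return(sum(ops$quadrature * conc[i, ]))
  }
  if (grepl("^mdfba", program$method)) {
    val <- 0
    M <- ncol(conc)
    if (program$mode %in% c("conc", "both")) {
      d <- cbind(conc[, 1] - x0,
                 conc[, -1, drop = FALSE] - conc[, -M, drop = FALSE])
      val <- val + sum(d^2)
    }
    if (program$mode %in% c("flux", "both")) {
      flux <- rbind(flux)
      d <- flux[, -1, drop = FALSE] - flux[, -ncol(flux), drop = FALSE]
      val <- val + sum(d^2)
    }
    return(val)
  }
  # R-DFBA: weighted indicator count
  a <- program$alpha
  wy <- if (program$mode == "both") 2 * a else 1
  wz <- if (program$mode == "both") 2 * (1 - a) else 1
  val <- 0
  if (program$has_y) val <- val + wy * sum(y)
  if (program$has_z) val <- val + wz * sum(z)
  val
}
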