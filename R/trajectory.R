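new_trajectory <- function(method, grid, times, x0, conc, flux, starts,
                           objective, status, residuals = NULL,
                           indicators = NULL, solver = NULL,
                           provenance = NULL) {
  structure(list(method = method, grid = grid, times = times, x0 = x0,
                 conc = conc, flux = flux, starts = starts,
                 objective = objective, status = status,
                 residuals = residuals, indicators = indicators,
                 solver = solver, provenance = provenance),
            class = "dfba_trajectory")
}

#' @export
print.dfba_trajectory <- function(x, ...) {
  cat(sprintf("<dfba_trajectory> method '%s', status %s, %d nodes\n",
              x$method, x$status, length(x$times)))
  if (!is.na(x$objective)) cat(sprintf(" objective: %.6g\n", x$objective))
  if (!is.null(x$residuals)) {
    cat(sprintf(" residuals: dynamics %.2e, continuity %.2e, bounds %.2e\n",
                x$residuals$dynamics, x$residuals$continuity,
                x$residuals$bounds))
  }
  invisible(x)
}

# decode a reduced-space solver point into a trajectory
decode_solution <- function(program, compiled, result) {
  ws <- compiled$meta$ws
  m <- program$model; g <- program$grid
  if (is.null(result$solution)) {
    return(new_trajectory(program$method, g, g$node_times,
                          stats::setNames(m$metabolites$x0,
                                          m$metabolites$id),
                          conc = NULL, flux = NULL, starts = NULL,
                          objective = NA_real_, status = result$status,
                          solver = result))
  }
  u <- result$solution
  V <- matrix(u[compiled$meta$iv], m$F, g$M, byrow = TRUE,
              dimnames = list(m$reactions$id, NULL))
  xf <- ws$x0rep + as.vector(ws$P %*% u[compiled$meta$iv])
  X <- matrix(xf, m$N, g$M, byrow = TRUE,
              dimnames = list(m$metabolites$id, NULL))
  f_nodes <- ws$S %*% V
  starts <- m$metabolites$x0 +
    t(ws$ops$G_start %*% t(f_nodes))
  rownames(starts) <- m$metabolites$id
  indicators <- NULL
  if (length(compiled$meta$iy) || length(compiled$meta$iz)) {
    indicators <- list()
    if (length(compiled$meta$iy)) {
      indicators$y <- matrix(u[compiled$meta$iy], m$N, g$M, byrow = TRUE,
                             dimnames = list(m$metabolites$id, NULL))
    }
    if (length(compiled$meta$iz)) {
      indicators$z <- matrix(u[compiled$meta$iz], m$F, g$M - 1,
                             byrow = TRUE,
                             dimnames = list(m$reactions$id, NULL))
    }
  }
  traj <- new_trajectory(
    program$method, g, g$node_times,
    stats::setNames(m$metabolites$x0, m$metabolites$id),
    conc = X, flux = V, starts = starts,
    objective = result$objective, status = result$status,
    indicators = indicators, solver = result)
  traj$residuals <- trajectory_residuals(program, traj)
  traj
}

#' Constraint residuals of a trajectory
#'
#' Maximum violations of the collocated dynamics
#' \eqn{\|dX/dt - S v\|_\infty} at the nodes (computed through the
#' derivative operator, independently of how the trajectory was
#' produced), of state continuity across element boundaries, of the
#' initial condition, and of the flux/concentration boxes.
#'
#' @param program The `dfba_program` the trajectory answers.
#' @param trajectory A `dfba_trajectory`.
#' @return List with `dynamics`, `continuity`, `initial`, `bounds`.
#' @export
trajectory_residuals <- function(program, trajectory) {
  m <- program$model; g <- program$grid
  S <- stoich_matrix(m)
  X <- trajectory$conc; V <- trajectory$flux
  starts <- trajectory$starts
  f <- S %*% V
  dyn <- 0; cont <- 0
  R <- g$R
  L_end <- lagrange_basis(c(0, g$roots), 1)  # element-end interpolation
  for (e in seq_len(g$E)) {
    cols <- ((e - 1) * R + 1):(e * R)
    D <- derivative_operator(g, e)
    support <- cbind(starts[, e], X[, cols, drop = FALSE])
    deriv <- support %*% t(D[-1, , drop = FALSE])
    dyn <- max(dyn, max(abs(deriv - f[, cols, drop = FALSE])))
    if (e < g$E) {
      # end value interpolated from the left element vs next start
      endv <- support %*% t(L_end)
      cont <- max(cont, max(abs(endv - starts[, e + 1])))
    }
  }
  list(
    dynamics = dyn,
    continuity = cont,
    initial = max(abs(starts[, 1] - trajectory$x0)),
    bounds = max(0,
                 program$x_lower - X, X - program$x_upper,
                 program$v_lower - V, V - program$v_upper)
  )
}

#' Solve a dynamic constraint-based program
#'
#' Compiles the program for the backend (eliminating the collocation
#' dynamics exactly), dispatches to the appropriate solver class
#' (LP/QP, smooth NLP with multistarts, or branch and bound for the
#' binary variants) and decodes the best feasible point into a node
#' trajectory.
#'
#' @param program A `dfba_program` from one of the builders.
#' @param seed Integer seed; the same (program, seed, options) triple
#'   reproduces the trajectory bit for bit.
#' @param multistart Number of deterministic restarts for nonconvex
#'   solves (overrides `options$multistart`).
#' @param options A [solver_options()].
#' @return A `dfba_trajectory` with fields `times`, `conc` (N x M),
#'   `flux` (F x M), element `starts`, `objective`, `status`,
#'   `residuals` and the raw solver result.
#' @export
solve_dfba <- function(program, seed = 1L, multistart = NULL,
                       options = solver_options()) {
  stopifnot(inherits(program, "dfba_program"))
  if (!is.null(multistart)) options$multistart <- multistart
  compiled <- compile_program(program)
  start <- NULL
  if (!length(compiled$prob$binary) && !is.null(compiled$prob$nl_ineq)) {
    # canonical first start: zero fluxes (state frozen at x0) with
    # indicators at their violation-driven values
    u0 <- pmin(pmax(rep(0, compiled$prob$n), compiled$prob$lb),
               compiled$prob$ub)
    if (!is.null(compiled$prob$heuristic)) {
      vals <- compiled$prob$heuristic(u0)
      u0[c(compiled$meta$iy, compiled$meta$iz)] <- vals
    }
    start <- u0
  }
  result <- solve_problem(compiled$prob, start = start,
                          options = options, seed = seed)
  decode_solution(program, compiled, result)
}
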