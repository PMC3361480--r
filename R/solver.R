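#' Solver options
#'
#' @param max_iter Iteration cap for the smooth (SLSQP) solver.
#' @param tol_feas Feasibility tolerance on returned points.
#' @param tol_gap Relative MIP gap at which branch-and-bound nodes are
#'   pruned against the incumbent.
#' @param tol_int Integrality tolerance for indicator variables.
#' @param max_nodes Branch-and-bound node cap ("best feasible" contract
#'   beyond it).
#' @param multistart Number of deterministic restarts for nonconvex
#'   smooth solves.
#' @param ridge Tikhonov ridge added to linear/quadratic objectives so
#'   the active-set QP solver sees a positive-definite Hessian; scaled by
#'   the objective magnitude internally.
#' @param time_limit_s Wall-clock cap for branch and bound (Inf keeps
#'   runs deterministic).
#' @param verbosity 0 silent, 1 node log.
#' @return List of class `solver_options`.
#' @export
solver_options <- function(max_iter = 2000, tol_feas = 1e-6,
                           tol_gap = 1e-4, tol_int = 1e-5,
                           max_nodes = 64, multistart = 1,
                           ridge = 1e-7, time_limit_s = Inf,
                           verbosity = 0) {
  structure(list(max_iter = max_iter, tol_feas = tol_feas,
                 tol_gap = tol_gap, tol_int = tol_int,
                 max_nodes = max_nodes, multistart = multistart,
                 ridge = ridge, time_limit_s = time_limit_s,
                 verbosity = verbosity),
            class = "solver_options")
}

#' Declarative optimization problem
#'
#' The pluggable contract between program construction and the solver
#' backends.  All problems are canonicalized to minimization; `sense =
#' "max"` negates the objective on input and restores the sign on
#' reported objective values.
#'
#' @param n Number of decision variables.
#' @param objective One of `list(type = "linear", c, const)`,
#'   `list(type = "quadratic", Q, c, const)` (minimizes
#'   `const + c'u + 1/2 u'Qu`), or `list(type = "nonlinear", fn, gr)`.
#' @param sense `"min"` or `"max"`.
#' @param lb,ub Finite variable bounds (length n).
#' @param lin_ineq `list(A, b)` imposing `A u <= b`, or NULL.
#' @param lin_eq `list(A, b)` imposing `A u = b`, or NULL.
#' @param nl_ineq `list(fn, jac, m)` imposing `fn(u) <= 0` (length m,
#'   `jac` returns the m x n Jacobian), or NULL.
#' @param binary Indices of binary variables (bounds must be within
#'   [0, 1]).
#' @param heuristic Optional `function(u_relax)` returning a candidate
#'   0/1 assignment for the binary variables (used to seed incumbents).
#' @param compile_leaf Optional `function(vals, center)` returning an
#'   equivalent smooth problem with the binaries fixed to `vals` (used by
#'   branch and bound to solve leaves with the LP/QP path).
#' @param name Label for printing.
#' @return An object of class `opt_problem`.
#' @export
opt_problem <- function(n, objective, sense = c("min", "max"),
                        lb = rep(-Inf, n), ub = rep(Inf, n),
                        lin_ineq = NULL, lin_eq = NULL, nl_ineq = NULL,
                        binary = integer(0), heuristic = NULL,
                        compile_leaf = NULL, name = "") {
  sense <- match.arg(sense)
  maximize <- sense == "max"
  if (maximize) {
    if (objective$type == "linear") {
      objective$c <- -objective$c
      objective$const <- -(objective$const %||% 0)
    } else if (objective$type == "quadratic") {
      objective$Q <- -objective$Q; objective$c <- -objective$c
      objective$const <- -(objective$const %||% 0)
    } else {
      fn0 <- objective$fn; gr0 <- objective$gr
      objective$fn <- function(u) -fn0(u)
      objective$gr <- function(u) -gr0(u)
    }
  }
  objective$const <- objective$const %||% 0
  stopifnot(length(lb) == n, length(ub) == n, all(lb <= ub))
  if (length(binary)) {
    stopifnot(all(lb[binary] >= 0), all(ub[binary] <= 1))
  }
  structure(list(n = n, objective = objective, maximize = maximize,
                 lb = lb, ub = ub, lin_ineq = lin_ineq, lin_eq = lin_eq,
                 nl_ineq = nl_ineq, binary = as.integer(binary),
                 heuristic = heuristic, compile_leaf = compile_leaf,
                 name = name),
            class = "opt_problem")
}

#' Backend capability declaration
#'
#' @return Tibble describing the shipped backends and the program
#'   classes they accept; honesty is exercised by the conformance tests.
#' @export
solver_capability <- function() {
  tibble::tibble(
    backend = c("quadprog", "slsqp", "branch_and_bound"),
    supports = c("LP, QP", "LP, QP, NLP", "MINLP"),
    deterministic = TRUE,
    tol_feas = 1e-6
  )
}

# objective value in the problem's internal (minimization) sense
eval_objective <- function(prob, u) {
  o <- prob$objective
  switch(o$type,
    linear = o$const + sum(o$c * u),
    quadratic = o$const + sum(o$c * u) + 0.5 * sum(u * (o$Q %*% u)),
    nonlinear = o$fn(u))
}

objective_gradient <- function(prob, u) {
  o <- prob$objective
  switch(o$type,
    linear = o$c,
    quadratic = o$c + as.vector(o$Q %*% u),
    nonlinear = o$gr(u))
}

# maximum constraint violation of a point
max_violation <- function(prob, u) {
  viol <- c(prob$lb - u, u - prob$ub)
  if (!is.null(prob$lin_ineq)) {
    viol <- c(viol, as.vector(prob$lin_ineq$A %*% u) - prob$lin_ineq$b)
  }
  if (!is.null(prob$lin_eq)) {
    viol <- c(viol, abs(as.vector(prob$lin_eq$A %*% u) - prob$lin_eq$b))
  }
  if (!is.null(prob$nl_ineq)) viol <- c(viol, prob$nl_ineq$fn(u))
  max(0, viol)
}

solver_result <- function(status, u, prob, iterations = NA_integer_,
                          message = "", gap = NA_real_) {
  obj <- if (is.null(u)) NA_real_ else eval_objective(prob, u)
  structure(list(
    status = status, solution = u,
    objective = if (prob$maximize) -obj else obj,
    objective_internal = obj,
    violation = if (is.null(u)) NA_real_ else max_violation(prob, u),
    iterations = iterations, gap = gap, message = message),
    class = "solver_result")
}

#' Solve a declarative optimization problem
#'
#' Dispatches on the program class: linear and quadratic objectives with
#' only linear constraints go to the dual active-set QP solver (linear
#' objectives receive a tiny documented ridge so the Hessian is positive
#' definite); smooth nonlinear programs go to SLSQP with analytic
#' Jacobians and deterministic seeded multistarts; problems with binary
#' variables go to [branch_and_bound()].
#'
#' @param prob An [opt_problem()].
#' @param start Optional start point (smooth nonconvex path only).
#' @param options A [solver_options()].
#' @param seed Integer seed controlling multistart draws.
#' @return A `solver_result`: `status` (optimal / feasible / infeasible /
#'   error), `solution`, `objective` (in the original sense),
#'   `violation`, `iterations`, `gap`, `message`.
#' @export
solve_problem <- function(prob, start = NULL, options = solver_options(),
                          seed = 1L) {
  stopifnot(inherits(prob, "opt_problem"))
  if (length(prob$binary)) {
    return(branch_and_bound(prob, options = options, seed = seed))
  }
  solve_smooth(prob, start = start, options = options, seed = seed)
}

solve_smooth <- function(prob, start = NULL, options = solver_options(),
                         seed = 1L) {
  smooth_class <- if (!is.null(prob$nl_ineq)) "NLP"
                  else if (prob$objective$type == "nonlinear") "NLP"
                  else if (prob$objective$type == "quadratic") "QP" else "LP"
  if (smooth_class %in% c("LP", "QP")) {
    solve_quadprog(prob, options)
  } else {
    solve_slsqp_multistart(prob, start, options, seed)
  }
}

# LP/QP path via quadprog::solve.QP (constraints t(Amat) u >= bvec)
solve_quadprog <- function(prob, options) {
  n <- prob$n
  o <- prob$objective
  if (o$type == "linear") {
    scale <- max(1, max(abs(o$c)))
    Q <- diag(options$ridge * scale, n)
    cvec <- o$c
  } else {
    Q <- as.matrix(o$Q)
    Q <- (Q + t(Q)) / 2
    scale <- max(1, max(abs(Q)), max(abs(o$c)))
    Q <- Q + diag(options$ridge * 0.1 * scale, n)
    cvec <- o$c
  }
  rows_eq <- NULL; b_eq <- numeric(0)
  fixed <- which(prob$lb == prob$ub)
  if (!is.null(prob$lin_eq)) {
    rows_eq <- prob$lin_eq$A; b_eq <- prob$lin_eq$b
  }
  if (length(fixed)) {
    Efix <- matrix(0, length(fixed), n)
    Efix[cbind(seq_along(fixed), fixed)] <- 1
    rows_eq <- rbind(rows_eq, Efix)
    b_eq <- c(b_eq, prob$lb[fixed])
  }
  free <- setdiff(seq_len(n), fixed)
  lo <- which(is.finite(prob$lb) & seq_len(n) %in% free)
  hi <- which(is.finite(prob$ub) & seq_len(n) %in% free)
  Ilo <- matrix(0, length(lo), n); Ilo[cbind(seq_along(lo), lo)] <- 1
  Ihi <- matrix(0, length(hi), n); Ihi[cbind(seq_along(hi), hi)] <- -1
  rows_ge <- rbind(Ilo, Ihi)
  b_ge <- c(prob$lb[lo], -prob$ub[hi])
  if (!is.null(prob$lin_ineq)) {
    rows_ge <- rbind(rows_ge, -prob$lin_ineq$A)
    b_ge <- c(b_ge, -prob$lin_ineq$b)
  }
  Amat <- t(rbind(rows_eq, rows_ge))
  bvec <- c(b_eq, b_ge)
  meq <- length(b_eq)
  res <- tryCatch(
    quadprog::solve.QP(Q, -cvec, Amat, bvec, meq = meq),
    error = function(e) e)
  if (inherits(res, "error")) {
    status <- if (grepl("inconsistent|no solution", conditionMessage(res)))
      "infeasible" else "error"
    return(solver_result(status, NULL, prob,
                         message = conditionMessage(res)))
  }
  u <- res$solution
  viol <- max_violation(prob, u)
  status <- if (viol <= options$tol_feas) "optimal" else "infeasible"
  solver_result(status, u, prob, iterations = res$iterations[1])
}

# smooth NLP path: SLSQP with analytic Jacobians, seeded multistarts
solve_slsqp_multistart <- function(prob, start, options, seed) {
  n <- prob$n
  starts <- list()
  base <- start %||% pmin(pmax((prob$lb + prob$ub) / 2, prob$lb), prob$ub)
  starts[[1]] <- base
  k <- max(1L, options$multistart)
  if (k > 1) {
    rng <- lcg_stream(seed)
    for (j in 2:k) {
      starts[[j]] <- prob$lb + rng(n) * (prob$ub - prob$lb)
    }
  }
  best <- NULL
  for (s in starts) {
    r <- solve_slsqp_once(prob, s, options)
    if (is.null(best) || better_result(r, best)) best <- r
    if (best$status == "optimal" && prob$objective$type != "nonlinear" &&
        is.null(prob$nl_ineq)) break
  }
  best
}

better_result <- function(a, b) {
  rank <- function(r) match(r$status, c("optimal", "feasible",
                                        "infeasible", "error"))
  if (rank(a) != rank(b)) return(rank(a) < rank(b))
  if (rank(a) <= 2) {
    return(!is.na(a$objective_internal) && !is.na(b$objective_internal) &&
             a$objective_internal < b$objective_internal - 1e-12)
  }
  FALSE
}

# deterministic uniform stream independent of R's global RNG state
# (Lehmer / Park-Miller multiplicative congruential generator)
lcg_stream <- function(seed) {
  state <- (as.double(seed) %% 2147483646) + 1
  function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (state * 48271) %% 2147483647
      out[i] <- state / 2147483647
    }
    out
  }
}

solve_slsqp_once <- function(prob, start, options) {
  n <- prob$n
  u0 <- pmin(pmax(start, prob$lb), prob$ub)
  has_lin <- !is.null(prob$lin_ineq)
  has_nl <- !is.null(prob$nl_ineq)
  g_fn <- function(u) {
    out <- numeric(0)
    if (has_lin) out <- c(out, as.vector(prob$lin_ineq$A %*% u) -
                            prob$lin_ineq$b)
    if (has_nl) out <- c(out, prob$nl_ineq$fn(u))
    out
  }
  g_jac <- function(u) {
    out <- NULL
    if (has_lin) out <- prob$lin_ineq$A
    if (has_nl) out <- rbind(out, prob$nl_ineq$jac(u))
    out
  }
  m_ineq <- (if (has_lin) nrow(prob$lin_ineq$A) else 0) +
    (if (has_nl) prob$nl_ineq$m else 0)
  args <- list(
    x0 = u0,
    eval_f = function(u) eval_objective(prob, u),
    eval_grad_f = function(u) objective_gradient(prob, u),
    lb = prob$lb, ub = prob$ub,
    opts = list(algorithm = "NLOPT_LD_SLSQP",
                maxeval = options$max_iter,
                xtol_rel = 1e-10, xtol_abs = 1e-10,
                tol_constraints_ineq = rep(options$tol_feas * 1e-2,
                                           m_ineq))
  )
  if (m_ineq > 0) {
    args$eval_g_ineq <- g_fn
    args$eval_jac_g_ineq <- g_jac
  } else {
    args$opts$tol_constraints_ineq <- NULL
  }
  if (!is.null(prob$lin_eq)) {
    args$eval_g_eq <- function(u) as.vector(prob$lin_eq$A %*% u) -
      prob$lin_eq$b
    args$eval_jac_g_eq <- function(u) prob$lin_eq$A
    args$opts$tol_constraints_eq <- rep(options$tol_feas * 1e-2,
                                        nrow(prob$lin_eq$A))
  }
  res <- tryCatch(do.call(nloptr::nloptr, args), error = function(e) e)
  if (inherits(res, "error")) {
    return(solver_result("error", NULL, prob,
                         message = conditionMessage(res)))
  }
  u <- pmin(pmax(res$solution, prob$lb), prob$ub)
  viol <- max_violation(prob, u)
  status <- if (viol > options$tol_feas) "infeasible"
            else if (res$status %in% 1:4) "optimal" else "feasible"
  solver_result(status, u, prob, iterations = res$iterations,
                message = res$message)
}
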