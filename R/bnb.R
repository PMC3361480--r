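#' Branch and bound over binary variables
#'
#' Best-first search over fixings of the binary variables; each node
#' solves the continuous relaxation (remaining binaries relaxed to their
#' [0, 1] boxes) with the smooth backend, warm-started from the parent
#' solution.  Incumbents come from relaxation solutions that are already
#' integral, from the problem's rounding heuristic, and from leaf solves
#' of fully fixed assignments (via `compile_leaf` when the problem
#' provides one, which turns R-DFBA leaves into plain LP/QPs).  Nodes
#' whose relaxation bound cannot beat the incumbent are pruned; for
#' nonconvex relaxations solved locally this pruning is heuristic and
#' the overall contract is "best feasible found", which is exact for
#' convex relaxations and verified against exhaustive enumeration on
#' small instances.
#'
#' @param prob An [opt_problem()] with a non-empty `binary` set.
#' @param options A [solver_options()]; `max_nodes` caps the search.
#' @param seed Seed for the relaxation multistarts.
#' @return A `solver_result` with a `gap` field (incumbent minus best
#'   open bound, in the minimization sense; 0 when the tree was
#'   exhausted).
#' @export
branch_and_bound <- function(prob, options = solver_options(), seed = 1L) {
  stopifnot(inherits(prob, "opt_problem"), length(prob$binary) > 0)
  bin <- prob$binary
  t_start <- Sys.time()
  # node relaxations of large indicator programs are themselves costly
  # NLPs; beyond ~20 binaries the tree cannot be exhausted anyway, so
  # the node cap tightens unless the caller raised it explicitly
  if (length(bin) > 20) {
    options$max_nodes <- min(options$max_nodes, 8L)
  }

  incumbent <- NULL     # solver_result (full problem, binaries integral)
  inc_obj <- Inf        # internal (minimization) objective

  consider <- function(res) {
    if (is.null(res$solution)) return(invisible(NULL))
    if (res$status %in% c("optimal", "feasible") &&
        max_violation(prob, res$solution) <= options$tol_feas &&
        all(abs(res$solution[bin] - round(res$solution[bin])) <=
              options$tol_int)) {
      u <- res$solution
      u[bin] <- round(u[bin])
      obj <- eval_objective(prob, u)
      if (obj < inc_obj - 1e-12) {
        inc_obj <<- obj
        incumbent <<- solver_result("feasible", u, prob)
      }
    }
    invisible(NULL)
  }

  solve_leaf <- function(vals, center) {
    if (!is.null(prob$compile_leaf)) {
      leaf <- prob$compile_leaf(vals, center)
      r <- solve_smooth(leaf, start = center, options = options,
                        seed = seed)
    } else {
      leaf <- prob
      leaf$lb[bin] <- vals; leaf$ub[bin] <- vals
      leaf$binary <- integer(0)
      st <- center
      if (!is.null(st)) st[bin] <- vals
      r <- solve_smooth(leaf, start = st, options = options, seed = seed)
    }
    if (!is.null(r$solution) && r$status %in% c("optimal", "feasible")) {
      u <- r$solution
      u[bin] <- vals
      consider(solver_result("feasible", u, prob))
    }
    invisible(NULL)
  }

  relax <- function(fix_idx, fix_val, start, node_seed) {
    p <- prob
    p$binary <- integer(0)
    if (length(fix_idx)) {
      p$lb[fix_idx] <- fix_val
      p$ub[fix_idx] <- fix_val
    }
    solve_smooth(p, start = start, options = options, seed = node_seed)
  }

  # seed an incumbent from the all-ones assignment, which is feasible
  # by construction for big-M indicator programs (and a cheap LP/QP)
  solve_leaf(rep(1, length(bin)), NULL)

  # root
  root <- relax(integer(0), numeric(0), NULL, seed)
  n_nodes <- 1L
  if (root$status %in% c("infeasible", "error") || is.null(root$solution)) {
    status <- if (is.null(incumbent)) "infeasible" else "feasible"
    out <- incumbent %||% solver_result(status, NULL, prob,
                                        message = root$message)
    out$status <- status
    out$gap <- if (is.null(incumbent)) NA_real_ else Inf
    return(out)
  }
  consider(root)
  if (!is.null(prob$heuristic)) {
    vals <- prob$heuristic(root$solution)
    if (!is.null(vals)) solve_leaf(vals, root$solution)
  } else {
    solve_leaf(round(root$solution[bin]), root$solution)
  }

  queue <- list(list(fix_idx = integer(0), fix_val = numeric(0),
                     bound = root$objective_internal,
                     start = root$solution, id = 0L))
  counter <- 0L
  exhausted <- TRUE

  while (length(queue) > 0) {
    if (n_nodes >= options$max_nodes ||
        as.numeric(difftime(Sys.time(), t_start, units = "secs")) >
          options$time_limit_s) {
      exhausted <- FALSE
      break
    }
    # best-first: smallest bound, then insertion order (deterministic)
    bounds <- vapply(queue, `[[`, numeric(1), "bound")
    ids <- vapply(queue, `[[`, integer(1), "id")
    pick <- order(bounds, ids)[1]
    node <- queue[[pick]]
    queue <- queue[-pick]
    prune_at <- if (is.finite(inc_obj))
      inc_obj - max(options$tol_gap * abs(inc_obj), 1e-9) else Inf
    if (node$bound >= prune_at) next

    free <- setdiff(bin, node$fix_idx)
    # resolve relaxation at this node (root already solved)
    if (length(node$fix_idx) == 0 && node$id == 0L) {
      res <- root
    } else {
      res <- relax(node$fix_idx, node$fix_val, node$start,
                   seed + node$id)
      n_nodes <- n_nodes + 1L
    }
    if (res$status %in% c("infeasible", "error") ||
        is.null(res$solution)) next
    if (res$objective_internal >= prune_at) next
    consider(res)
    yfrac <- abs(res$solution[free] - round(res$solution[free]))
    if (length(free) == 0 || all(yfrac <= options$tol_int)) {
      # integral relaxation: this subtree is done
      if (length(free)) {
        solve_leaf_full <- c(node$fix_val,
                             round(res$solution[free]))
        solve_leaf(solve_leaf_full[match(bin, c(node$fix_idx, free))],
                   res$solution)
      }
      next
    }
    if (!is.null(prob$heuristic)) {
      vals <- prob$heuristic(res$solution)
      if (!is.null(vals)) solve_leaf(vals, res$solution)
    }
    jb <- free[order(-yfrac, free)[1]]
    for (val in c(round(res$solution[jb]), 1 - round(res$solution[jb]))) {
      counter <- counter + 1L
      child <- list(fix_idx = c(node$fix_idx, jb),
                    fix_val = c(node$fix_val, val),
                    bound = res$objective_internal,
                    start = res$solution, id = counter)
      if (length(child$fix_idx) == length(bin)) {
        solve_leaf(child$fix_val[match(bin, child$fix_idx)],
                   res$solution)
        n_nodes <- n_nodes + 1L
      } else {
        queue <- c(queue, list(child))
      }
    }
    if (options$verbosity > 0) {
      message(sprintf("bnb node %d: bound %.6g incumbent %.6g open %d",
                      n_nodes, res$objective_internal, inc_obj,
                      length(queue)))
    }
  }

  if (is.null(incumbent)) {
    return(solver_result(if (exhausted) "infeasible" else "error",
                         NULL, prob, iterations = n_nodes))
  }
  open_bounds <- vapply(queue, `[[`, numeric(1), "bound")
  lower <- min(c(open_bounds, inc_obj))
  out <- incumbent
  out$status <- if (exhausted) "optimal" else "feasible"
  out$iterations <- n_nodes
  out$gap <- if (exhausted) 0 else inc_obj - lower
  out
}
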