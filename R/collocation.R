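#' Roots of the shifted Legendre polynomial on the unit interval
#'
#' Collocation points are the Gauss-Legendre roots, i.e. the roots of the
#' Legendre polynomial of the requested order shifted to \eqn{(0, 1)}.  All
#' roots are interior and symmetric about 0.5; for odd orders the middle
#' root is exactly 0.5.
#'
#' @param order Polynomial order, an integer between 1 and 12.
#' @return Numeric vector of `order` strictly increasing roots in (0, 1).
#' @examples
#' legendre_roots(1)   # 0.5
#' legendre_roots(5)
#' @export
legendre_roots <- function(order) {
  order <- check_order(order)
  if (order == 1) return(0.5)
  r <- pracma::gaussLegendre(order, 0, 1)$x
  # enforce exact symmetry (gaussLegendre is symmetric to ~1e-16 already)
  r <- (r + rev(1 - r)) / 2
  if (order %% 2 == 1) r[(order + 1) / 2] <- 0.5
  r
}

# Gauss-Legendre quadrature weights on (0,1), matching legendre_roots()
legendre_weights <- function(order) {
  order <- check_order(order)
  if (order == 1) return(1)
  w <- pracma::gaussLegendre(order, 0, 1)$w
  (w + rev(w)) / 2
}

check_order <- function(order) {
  if (length(order) != 1 || !is.finite(order) || order != round(order) ||
      order < 1 || order > 12) {
    dynfba_abort("`order` must be a single integer between 1 and 12",
                 class = "dynfba_order_error")
  }
  as.integer(order)
}

#' Collocation grid over finite elements
#'
#' Divides the horizon \eqn{[t_0, t_f]} into `elements` uniform finite
#' elements and places the roots of the order-`order` Legendre polynomial
#' inside each element.  States and fluxes are parameterized at these
#' \eqn{M = E \cdot order} nodes; the element start points serve as extra
#' interpolation support nodes carrying the initial condition and the
#' continuity constraints.
#'
#' @param t0,tf Horizon endpoints, in the time units of the model.
#' @param elements Number of finite elements (\eqn{E \ge 1}).
#' @param order Legendre polynomial order (roots per element).
#' @return An object of class `collocation_grid` with fields `t0`, `tf`,
#'   `E`, `order`, `R`, `element_bounds` (length E+1), `widths`, `roots`
#'   (unit-interval roots), `unit_weights` (Gauss weights), `node_times`
#'   (all M node times, strictly increasing) and `M`.
#' @examples
#' g <- collocation_grid(0, 10, elements = 5, order = 5)
#' g$M                 # 25
#' g$element_bounds    # 0 2 4 6 8 10
#' @export
collocation_grid <- function(t0, tf, elements, order) {
  if (!is.finite(t0) || !is.finite(tf) || tf <= t0) {
    dynfba_abort("horizon must satisfy t0 < tf with finite endpoints",
                 class = "dynfba_grid_error")
  }
  if (length(elements) != 1 || elements < 1 || elements != round(elements)) {
    dynfba_abort("`elements` must be a positive integer",
                 class = "dynfba_grid_error")
  }
  E <- as.integer(elements)
  order <- check_order(order)
  bounds <- seq(t0, tf, length.out = E + 1)
  widths <- diff(bounds)
  roots <- legendre_roots(order)
  node_times <- as.vector(vapply(
    seq_len(E), function(e) bounds[e] + widths[e] * roots, numeric(order)
  ))
  structure(
    list(t0 = t0, tf = tf, E = E, order = order, R = order,
         element_bounds = bounds, widths = widths, roots = roots,
         unit_weights = legendre_weights(order),
         node_times = node_times, M = E * order),
    class = "collocation_grid"
  )
}

#' @export
print.collocation_grid <- function(x, ...) {
  cat(sprintf(
    "<collocation_grid> [%g, %g], %d elements x order %d = %d nodes\n",
    x$t0, x$tf, x$E, x$order, x$M))
  invisible(x)
}

# Lagrange basis over support points `tau`, evaluated at points `t`.
# Returns length(t) x length(tau) matrix.
lagrange_basis <- function(tau, t) {
  K <- length(tau)
  out <- matrix(0, length(t), K)
  for (k in seq_len(K)) {
    num <- rep(1, length(t))
    for (m in seq_len(K)[-k]) num <- num * (t - tau[m]) / (tau[k] - tau[m])
    out[, k] <- num
  }
  out
}

# Derivative of the Lagrange basis over `tau`, evaluated at points `t`.
lagrange_basis_deriv <- function(tau, t) {
  K <- length(tau)
  out <- matrix(0, length(t), K)
  for (k in seq_len(K)) {
    acc <- rep(0, length(t))
    for (m in seq_len(K)[-k]) {
      term <- rep(1 / (tau[k] - tau[m]), length(t))
      for (n in seq_len(K)[-c(k, m)]) {
        term <- term * (t - tau[n]) / (tau[k] - tau[n])
      }
      acc <- acc + term
    }
    out[, k] <- acc
  }
  out
}

#' Collocation derivative operator of one finite element
#'
#' The state inside element `e` is the degree-`order` polynomial through
#' its value at the element start and at the `order` collocation roots.
#' The derivative operator maps these `order + 1` support values to the
#' time-derivative of that polynomial at the same support points, scaled
#' by the element width.  Rows 2 to `order + 1` (the roots) are the rows
#' at which the dynamics \eqn{dX/dt = S v} are collocated.
#'
#' @param grid A [collocation_grid()].
#' @param element Element index in `1:grid$E`.
#' @return A square (order+1) x (order+1) matrix `D` such that
#'   `D %*% values` gives d/dt of the interpolating polynomial at
#'   (element start, roots).
#' @export
derivative_operator <- function(grid, element) {
  stopifnot(inherits(grid, "collocation_grid"))
  if (element < 1 || element > grid$E) {
    dynfba_abort("invalid element index", class = "dynfba_grid_error")
  }
  tau <- c(0, grid$roots)
  lagrange_basis_deriv(tau, tau) / grid$widths[element]
}

# Element integration matrix: A[r, k] = integral_0^{tau_r} L_k(s) ds
# where L_k is the Lagrange basis over the unit roots.  Computed by
# 20-point Gauss quadrature, exact for the polynomial integrand.
element_integration <- function(roots) {
  R <- length(roots)
  q <- pracma::gaussLegendre(20, 0, 1)
  A <- matrix(0, R, R)
  for (r in seq_len(R)) {
    xs <- q$x * roots[r]
    ws <- q$w * roots[r]
    A[r, ] <- colSums(lagrange_basis(roots, xs) * ws)
  }
  A
}

#' Collocation integration operator
#'
#' The inverse view of the collocation dynamics: if `f` holds nodal values
#' of the state derivative (\eqn{S v} at the collocation nodes, globally
#' ordered), then `G %*% f` gives the nodal values of the state relative
#' to its initial value, with exact polynomial integration inside each
#' element and exact carry-over of the element end value to the next
#' element start.  A state trajectory written as
#' \eqn{x = x_0 + G f} therefore satisfies the collocated dynamics, the
#' continuity constraints and the initial condition identically.
#'
#' @param grid A [collocation_grid()].
#' @return List with `G` (M x M dense), `G_start` (E x M; row e maps `f`
#'   to the element-e start value relative to x0) and `quadrature`
#'   (length-M Gauss weights for integrals over the whole horizon).
#' @export
integration_operator <- function(grid) {
  stopifnot(inherits(grid, "collocation_grid"))
  R <- grid$R; E <- grid$E; M <- grid$M
  A <- element_integration(grid$roots)
  q <- grid$unit_weights
  G <- matrix(0, M, M)
  G_start <- matrix(0, E, M)
  for (e in seq_len(E)) {
    rows <- ((e - 1) * R + 1):(e * R)
    if (e > 1) {
      prev <- seq_len((e - 1) * R)
      carry <- rep(grid$widths[rep(seq_len(e - 1), each = R)] * rep(q, e - 1))
      G_start[e, prev] <- carry
      G[rows, prev] <- matrix(rep(carry, each = R), nrow = R)
    }
    G[rows, rows] <- grid$widths[e] * A
  }
  list(G = G, G_start = G_start,
       quadrature = rep(grid$widths, each = R) * rep(q, E))
}

#' Decision-variable counts of the collocation parameterization
#'
#' Both metabolite concentrations and reaction fluxes are parameterized at
#' every collocation node, so a network with `n_met` metabolites and
#' `n_rxn` reactions discretized on a grid with \eqn{M = E \cdot order}
#' nodes carries \eqn{n_{met} M} concentration unknowns and
#' \eqn{n_{rxn} M} flux unknowns.
#'
#' @param n_met,n_rxn Metabolite and reaction counts (non-negative).
#' @param grid A [collocation_grid()].
#' @return A one-row tibble with `n_conc`, `n_flux`, `n_total`.
#' @examples
#' g <- collocation_grid(0, 24, 12, 5)
#' count_variables(6, 7, g)$n_total   # 780
#' @export
count_variables <- function(n_met, n_rxn, grid) {
  stopifnot(inherits(grid, "collocation_grid"), n_met >= 0, n_rxn >= 0)
  tibble::tibble(
    n_conc = as.integer(n_met * grid$M),
    n_flux = as.integer(n_rxn * grid$M),
    n_total = as.integer((n_met + n_rxn) * grid$M)
  )
}

#' Interpolate piecewise-polynomial states at arbitrary times
#'
#' Evaluates the collocation polynomial of each state inside the element
#' containing `t`, using the element start value and the node values as
#' Lagrange support.  Values at node times are reproduced exactly.
#'
#' @param grid A [collocation_grid()].
#' @param start_values States x E matrix of element start values (element
#'   1 starts at the initial condition).
#' @param node_values States x M matrix of values at collocation nodes.
#' @param t Query times inside the horizon.
#' @return States x length(t) matrix.
#' @export
interpolate_states <- function(grid, start_values, node_values, t) {
  stopifnot(inherits(grid, "collocation_grid"))
  start_values <- rbind(start_values)
  node_values <- rbind(node_values)
  if (any(t < grid$t0 - 1e-12) || any(t > grid$tf + 1e-12)) {
    dynfba_abort("query time outside the horizon",
                 class = "dynfba_grid_error")
  }
  R <- grid$R
  out <- matrix(NA_real_, nrow(node_values), length(t))
  elem <- pmin(pmax(findInterval(t, grid$element_bounds,
                                 rightmost.closed = TRUE), 1), grid$E)
  for (e in unique(elem)) {
    sel <- which(elem == e)
    tloc <- (t[sel] - grid$element_bounds[e]) / grid$widths[e]
    L <- lagrange_basis(c(0, grid$roots), tloc)
    support <- cbind(start_values[, e, drop = FALSE],
                     node_values[, ((e - 1) * R + 1):(e * R), drop = FALSE])
    out[, sel] <- support %*% t(L)
  }
  # stored values are reproduced bit for bit at node and start times
  hit <- match(t, grid$node_times)
  if (any(!is.na(hit))) {
    out[, !is.na(hit)] <- node_values[, hit[!is.na(hit)], drop = FALSE]
  }
  hs <- match(t, grid$element_bounds[seq_len(grid$E)])
  if (any(!is.na(hs))) {
    out[, !is.na(hs)] <- start_values[, hs[!is.na(hs)], drop = FALSE]
  }
  rownames(out) <- rownames(node_values)
  out
}
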