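test_that("Legendre roots match an independent bracketing root-finder", {
  for (n in c(1, 2, 3, 5, 8, 12)) {
    r <- legendre_roots(n)
    expect_length(r, n)
    expect_true(all(r > 0 & r < 1))
    # symmetry about the interval midpoint
    expect_equal(r, rev(1 - r), tolerance = 1e-14)
    if (n %% 2 == 1) expect_identical(r[(n + 1) / 2], 0.5)
    if (n > 1) {
      expect_true(max(abs(r - oracle_legendre_roots(n))) <= 1e-12)
    }
  }
  expect_identical(legendre_roots(1), 0.5)
  expect_error(legendre_roots(0), class = "dynfba_order_error")
  expect_error(legendre_roots(13), class = "dynfba_order_error")
})

test_that("grids partition the horizon uniformly with interior nodes", {
  g <- collocation_grid(0, 10, 5, 5)
  expect_equal(g$element_bounds, c(0, 2, 4, 6, 8, 10))
  expect_equal(g$M, 25)
  expect_true(!is.unsorted(g$node_times, strictly = TRUE))
  # roots stay strictly inside their element
  for (e in 1:5) {
    nodes <- g$node_times[((e - 1) * 5 + 1):(e * 5)]
    expect_true(all(nodes > g$element_bounds[e] &
                      nodes < g$element_bounds[e + 1]))
  }
  g24 <- collocation_grid(0, 24, 12, 5)
  expect_equal(unique(round(diff(g24$element_bounds), 12)), 2)
  g1 <- collocation_grid(0, 1, 1, 1)
  expect_equal(g1$node_times, 0.5)
  expect_error(collocation_grid(0, 0, 5, 5), class = "dynfba_grid_error")
  expect_error(collocation_grid(0, -1, 5, 5), class = "dynfba_grid_error")
})

test_that("derivative operator annihilates constants and is exact on polynomials", {
  g <- collocation_grid(2, 7, 3, 5)
  for (e in 1:3) {
    D <- derivative_operator(g, e)
    support_t <- c(g$element_bounds[e],
                   g$element_bounds[e] + g$widths[e] * g$roots)
    expect_equal(as.vector(D %*% rep(3.7, 6)), rep(0, 6),
                 tolerance = 1e-11)
    expect_equal(as.vector(D %*% support_t), rep(1, 6),
                 tolerance = 1e-10)
    # f(t) = t^2 on the element: derivative 2 t at each support point
    expect_equal(as.vector(D %*% support_t^2), 2 * support_t,
                 tolerance = 1e-9)
    # random degree-5 polynomial, exact derivative at the roots
    cf <- c(0.3, -1.2, 0.8, 2.1, -0.4, 0.05)
    f <- sapply(support_t, function(t) sum(cf * t^(0:5)))
    df <- sapply(support_t, function(t) sum(cf[-1] * (1:5) * t^(0:4)))
    expect_equal(as.vector(D %*% f), df, tolerance = 1e-8)
  }
  expect_error(derivative_operator(g, 4), class = "dynfba_grid_error")
})

test_that("integration operator solves a linear ODE to collocation accuracy", {
  # dx/dt = -x, x(0) = 1 on [0,1]: solve (I + G) x = 1 and compare
  # against the exact exponential at the nodes
  g <- collocation_grid(0, 1, 5, 5)
  G <- integration_operator(g)$G
  x <- solve(diag(g$M) + G, rep(1, g$M))
  expect_lt(max(abs(x - exp(-g$node_times))), 1e-6)
})

test_that("quadrature weights integrate polynomials exactly", {
  g <- collocation_grid(0, 3, 4, 4)
  wq <- integration_operator(g)$quadrature
  # exact through degree 2*order-1 = 7
  for (p in 0:7) {
    expect_equal(sum(wq * g$node_times^p), 3^(p + 1) / (p + 1),
                 tolerance = 1e-10)
  }
})

test_that("variable counts follow the closed form (N+F)*E*order", {
  g <- collocation_grid(0, 10, 5, 5)
  cnt <- count_variables(1136, 2251, g)
  expect_identical(cnt$n_conc, 28400L)
  expect_identical(cnt$n_flux, 56275L)
  g24 <- collocation_grid(0, 24, 12, 5)
  expect_identical(count_variables(6, 7, g24)$n_total, 780L)
  expect_equal(unlist(count_variables(0, 0, g)), c(n_conc = 0,
                                                   n_flux = 0,
                                                   n_total = 0))
  for (case in list(c(3, 4, 2, 3), c(1, 1, 1, 1), c(10, 2, 7, 6))) {
    gg <- collocation_grid(0, 1, case[3], case[4])
    expect_equal(count_variables(case[1], case[2], gg)$n_total,
                 (case[1] + case[2]) * case[3] * case[4])
  }
})

test_that("interpolation reproduces nodes exactly and low-degree polynomials everywhere", {
  g <- collocation_grid(0, 2, 2, 5)
  # states: a constant and t^3
  starts <- rbind(rep(4.2, g$E),
                  g$element_bounds[seq_len(g$E)]^3)
  nodes <- rbind(rep(4.2, g$M), g$node_times^3)
  # node times: bit-exact reproduction
  vals <- interpolate_states(g, starts, nodes, g$node_times)
  expect_identical(vals[1, ], nodes[1, ])
  expect_identical(vals[2, ], nodes[2, ])
  # arbitrary interior points: polynomial reproduced to rounding
  tq <- seq(0.05, 1.95, by = 0.1)
  vq <- interpolate_states(g, starts, nodes, tq)
  expect_equal(vq[1, ], rep(4.2, length(tq)), tolerance = 1e-12)
  expect_equal(vq[2, ], tq^3, tolerance = 1e-10)
  expect_error(interpolate_states(g, starts, nodes, 2.5),
               class = "dynfba_grid_error")
})
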