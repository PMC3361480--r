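# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths.

# shifted Legendre polynomial P_n(2t - 1) via the three-term recurrence,
# and its roots by sign-change bracketing + uniroot
shifted_legendre <- function(n, t) {
  x <- 2 * t - 1
  pm1 <- rep(1, length(x)); p <- x
  if (n == 0) return(pm1)
  if (n == 1) return(p)
  for (k in 2:n) {
    pk <- ((2 * k - 1) * x * p - (k - 1) * pm1) / k
    pm1 <- p; p <- pk
  }
  p
}

oracle_legendre_roots <- function(n) {
  grid <- seq(1e-9, 1 - 1e-9, length.out = 4000)
  vals <- shifted_legendre(n, grid)
  sgn <- which(diff(sign(vals)) != 0)
  vapply(sgn, function(i) {
    stats::uniroot(function(t) shifted_legendre(n, t),
                   c(grid[i], grid[i + 1]), tol = 1e-15)$root
  }, numeric(1))
}

# residual sum of squares by naive loop accumulation
oracle_rss <- function(y, f) {
  acc <- 0
  for (j in seq_along(y)) acc <- acc + (y[j] - f[j])^2
  acc
}

# Kendall tau-b by exhaustive pair counting with tie adjustment
oracle_tau_b <- function(a, b) {
  n <- length(a)
  conc <- 0; disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(a[i] - a[j]) * sign(b[i] - b[j])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  t1 <- sum(sapply(table(a), function(m) m * (m - 1) / 2))
  t2 <- sum(sapply(table(b), function(m) m * (m - 1) / 2))
  den <- sqrt((n0 - t1) * (n0 - t2))
  if (den == 0) return(NA_real_)
  (conc - disc) / den
}

# exhaustive enumeration of a binary program: solve every 0/1 assignment
# with the same smooth subsolver and keep the best feasible leaf
oracle_enumerate_binaries <- function(prob, options = solver_options()) {
  bin <- prob$binary
  k <- length(bin)
  best <- NULL
  for (code in 0:(2^k - 1)) {
    vals <- as.integer(intToBits(code))[seq_len(k)]
    leaf <- prob
    leaf$binary <- integer(0)
    leaf$lb[bin] <- vals; leaf$ub[bin] <- vals
    r <- solve_problem(leaf, options = options)
    if (r$status %in% c("optimal", "feasible")) {
      obj <- r$objective_internal
      if (is.null(best) || obj < best$objective_internal - 1e-12) {
        best <- r
        best$assignment <- vals
      }
    }
  }
  best
}

# random convex mixed-binary toy instance (LP in the continuous part),
# guaranteed feasible by construction around a random interior point
random_milp_instance <- function(seed, n_cont = 2, n_bin = NULL) {
  rng <- local({
    state <- seed * 7919 + 13
    function(n = 1) {
      out <- numeric(n)
      for (i in seq_len(n)) {
        state <<- (state * 48271) %% 2147483647
        out[i] <- state / 2147483647
      }
      out
    }
  })
  if (is.null(n_bin)) n_bin <- 2 + floor(rng() * 5)   # 2..6 binaries
  n <- n_cont + n_bin
  m <- 2 + floor(rng() * 3)
  A <- matrix(round(rng(m * n) * 4 - 2, 2), m, n)
  xbar <- c(rng(n_cont) * 2, round(rng(n_bin)))
  b <- as.vector(A %*% xbar) + rng(m) * 0.5
  cvec <- round(rng(n) * 4 - 2, 2)
  opt_problem(
    n, list(type = "linear", c = cvec, const = 0), sense = "min",
    lb = c(rep(0, n_cont), rep(0, n_bin)),
    ub = c(rep(3, n_cont), rep(1, n_bin)),
    lin_ineq = list(A = A, b = b),
    binary = n_cont + seq_len(n_bin),
    name = sprintf("milp_toy_%d", seed))
}

# random small stoichiometric model (2 metabolites in a chain A -> B,
# plus an exchange), used for relaxation-bound checks
random_small_model <- function(seed) {
  rng <- local({
    state <- seed * 104729 + 7
    function(n = 1) {
      out <- numeric(n)
      for (i in seq_len(n)) {
        state <<- (state * 48271) %% 2147483647
        out[i] <- state / 2147483647
      }
      out
    }
  })
  v1 <- 0.5 + rng() * 2
  v2 <- 0.5 + rng() * 2
  stoich_model(
    metabolites = tibble::tibble(
      id = c("A", "B"),
      x0 = c(1 + rng(), 1 + rng()),
      x_min = 0, x_max = 10),
    reactions = tibble::tibble(
      id = c("r1", "r2"),
      equation = c("A -> B", "B -> A"),
      v_min = 0, v_max = c(v1, v2)))
}
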