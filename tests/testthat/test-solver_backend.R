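test_that("LP and QP conformance: analytic optima are recovered", {
  # max v subject to 0 <= v <= 8
  lp <- opt_problem(1, list(type = "linear", c = 1), sense = "max",
                    lb = 0, ub = 8)
  r <- solve_problem(lp)
  expect_equal(r$status, "optimal")
  expect_equal(r$solution, 8, tolerance = 1e-7)
  expect_equal(r$objective, 8, tolerance = 1e-6)
  # min (x-3)^2 subject to 0 <= x <= 2: optimum at the bound, value 1
  qp <- opt_problem(1, list(type = "quadratic", Q = matrix(2), c = -6,
                            const = 9),
                    sense = "min", lb = 0, ub = 2)
  r2 <- solve_problem(qp)
  expect_equal(r2$solution, 2, tolerance = 1e-7)
  expect_equal(r2$objective, 1, tolerance = 1e-6)
  # infeasible linear rows are reported, not raised
  bad <- opt_problem(1, list(type = "linear", c = 1), lb = 0, ub = 1,
                     lin_ineq = list(A = rbind(1, -1), b = c(-2, -2)))
  expect_equal(solve_problem(bad)$status, "infeasible")
})

test_that("declared backend capabilities are honest", {
  caps <- solver_capability()
  expect_true(any(grepl("NLP", caps$supports)))
  expect_true(any(grepl("MINLP", caps$supports)))
  # the smooth NLP path handles a nonlinear constraint: minimize x + y
  # outside the unit circle in the box; the optimum touches the circle
  # at a coordinate axis with value 1
  nlp <- opt_problem(
    2, list(type = "linear", c = c(1, 1)), lb = c(0, 0), ub = c(2, 2),
    nl_ineq = list(fn = function(u) 1 - sum(u^2),
                   jac = function(u) -2 * rbind(u), m = 1))
  r <- solve_problem(nlp, start = c(1.5, 0.5),
                     options = solver_options(multistart = 3))
  expect_true(r$status %in% c("optimal", "feasible"))
  expect_gte(sum(r$solution^2), 1 - 1e-6)
  expect_equal(r$objective, 1, tolerance = 1e-4)
})

test_that("MINLP conformance: indicator forced on by a big-M row", {
  # min y subject to x - 10 y <= 1 with x pinned at 5: y must be 1
  p <- opt_problem(2, list(type = "linear", c = c(0, 1)),
                   lb = c(5, 0), ub = c(5, 1),
                   lin_ineq = list(A = rbind(c(1, -10)), b = 1),
                   binary = 2L)
  r <- solve_problem(p)
  expect_equal(r$status, "optimal")
  expect_equal(r$solution[2], 1)
  expect_equal(r$objective, 1, tolerance = 1e-8)
})

test_that("branch and bound explores only the root when it is integral", {
  # relaxation optimum already binary: min y with no coupling
  p <- opt_problem(2, list(type = "linear", c = c(0, 1)),
                   lb = c(0, 0), ub = c(1, 1), binary = 2L)
  r <- solve_problem(p)
  expect_equal(r$status, "optimal")
  expect_equal(r$iterations, 1)
  expect_equal(r$objective, 0)
})

test_that("a 2-binary toy matches exhaustive 4-leaf enumeration", {
  # optimum requires y = (1, 0): y1 relaxes a row that x needs, y2 is
  # purely penalized
  p <- opt_problem(
    3, list(type = "linear", c = c(-1, 2, 3)),
    lb = c(0, 0, 0), ub = c(4, 1, 1),
    lin_ineq = list(A = rbind(c(1, -4, 0)), b = 0.5),
    binary = c(2L, 3L))
  bb <- solve_problem(p)
  ex <- oracle_enumerate_binaries(p)
  expect_equal(bb$objective, ex$objective, tolerance = 1e-6)
  expect_equal(round(bb$solution[2:3]), c(1, 0))
})

test_that("branch and bound equals brute force on seeded random MILP toys", {
  mismatches <- 0
  for (s in 1:50) {
    prob <- random_milp_instance(s)
    bb <- solve_problem(prob)
    ex <- oracle_enumerate_binaries(prob)
    if (is.null(ex)) {
      expect_true(bb$status %in% c("infeasible", "error"))
    } else {
      expect_true(bb$status %in% c("optimal", "feasible"))
      if (abs(bb$objective - ex$objective) > 1e-6) {
        mismatches <- mismatches + 1
      }
    }
  }
  expect_equal(mismatches, 0)
})

test_that("pruning never discards the true optimum on 3-binary toys", {
  for (s in 101:110) {
    prob <- random_milp_instance(s, n_bin = 3)
    bb <- solve_problem(prob)
    ex <- oracle_enumerate_binaries(prob)
    if (!is.null(ex)) {
      expect_lte(bb$objective, ex$objective + 1e-6)
      expect_gte(bb$objective, ex$objective - 1e-6)
    }
  }
})

test_that("identical problem and seed return identical points", {
  prob <- random_milp_instance(7)
  a <- solve_problem(prob, seed = 3)
  b <- solve_problem(prob, seed = 3)
  expect_identical(a$solution, b$solution)
  expect_identical(a$objective, b$objective)
})
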