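small_model <- function() {
  stoich_model(
    tibble::tibble(id = c("A", "B"), x0 = c(2, 1), x_max = 10),
    tibble::tibble(id = c("r1", "r2"), equation = c("A -> B", "B -> A"),
                   v_min = 0, v_max = c(1.5, 1)))
}

test_that("program construction records variables, modes and integrality", {
  m <- calvin_model()
  g <- collocation_grid(0, 10, 5, 5)
  p <- build_dfba(m, g, "Sink")
  d <- program_dims(p)
  expect_equal(d$n_node_total, 325)   # (6+7) * 25 node variables
  expect_equal(d$n_conc, 150)
  expect_equal(d$n_flux, 175)
  expect_equal(d$n_indicator, 0)
  expect_false(p$binary)
  expect_error(build_dfba(m, g, "NotHere"), "unknown metabolite")

  p2 <- build_rdfba(m, g, "both", relaxed = FALSE)
  d2 <- program_dims(p2)
  expect_equal(d2$n_indicator, 150 + 7 * 24)
  expect_true(p2$binary)
  p3 <- build_rdfba(m, g, "conc", relaxed = TRUE)
  expect_false(p3$binary)
  expect_error(
    build_rdfba(m, g, "conc", relaxed = TRUE,
                thresholds = threshold_params(0.4, 0, 0, 0)),
    "zero tolerances")
  expect_error(build_mdfba(m, g, "nope"))
  # the ten-method dispatcher covers the whole vocabulary
  for (tag in dfba_methods()) {
    expect_s3_class(build_method(tag, m, g), "dfba_program")
  }
})

test_that("fluctuation objectives evaluate as the printed sums", {
  m <- stoich_model(
    tibble::tibble(id = "A", x0 = 1, x_max = 10),
    tibble::tibble(id = "r", equation = "A -> 2 A", v_max = 1))
  # one metabolite, three nodes; x = (X0=1, then 2, 4)... the first
  # difference is against the initial condition
  g <- collocation_grid(0, 1, 1, 3)
  p <- build_mdfba(m, g, "conc")
  expect_equal(objective_value(p, conc = rbind(c(2, 4, 4))),
               (2 - 1)^2 + (4 - 2)^2 + 0)
  # the worked example: nodes (2, 4) after X0 = 1 give 1 + 4 = 5
  g2 <- collocation_grid(0, 1, 1, 2)
  p2 <- build_mdfba(m, g2, "conc")
  expect_equal(objective_value(p2, conc = rbind(c(2, 4))), 5)
  # constant trajectories at X0 score zero
  expect_equal(objective_value(p, conc = rbind(c(1, 1, 1))), 0)
  # additivity of the combined mode
  mC <- calvin_model()
  gC <- collocation_grid(0, 10, 2, 3)
  X <- matrix(rexp(6 * 6, 1), 6, 6)
  V <- matrix(rexp(7 * 6, 1), 7, 6)
  both <- objective_value(build_mdfba(mC, gC, "both"), X, V)
  conc <- objective_value(build_mdfba(mC, gC, "conc"), X)
  flux <- objective_value(build_mdfba(mC, gC, "flux"), X, V)
  expect_equal(both, conc + flux)
  # flux differences start at the second node: a single-column flux
  # matrix contributes nothing
  expect_equal(objective_value(build_mdfba(m, g2, "flux"),
                               conc = rbind(c(1, 1)),
                               flux = rbind(c(3, 3))), 0)
})

test_that("on/off thresholds follow the printed band formula", {
  # x_prev = 2.0 with gamma_x = 0.4, eps_x = 0.01: band (1.19, 2.81)
  th <- dynfba:::conc_thresholds(2, 0.4, 0.01, 0, 20)
  expect_equal(th$wu, 2.81)
  expect_equal(th$wl, 1.19)
  # clipping into the concentration box
  th2 <- dynfba:::conc_thresholds(0.1, 0.4, 0.01, 0.5, 20)
  expect_equal(th2$wl, 0.5)
  thv <- dynfba:::flux_thresholds(1, 0.2, 0.05, 0, 10)
  expect_equal(thv$bu, 1.25)
  expect_equal(thv$bl, 0.75)
})

test_that("DFBA drives a single uncapacitated route to its bound", {
  m <- stoich_model(
    tibble::tibble(id = c("A", "B"), x0 = c(5, 0), x_max = 50),
    tibble::tibble(id = "r", equation = "A -> B", v_max = 2))
  g <- collocation_grid(0, 1, 2, 3)
  tr <- solve_dfba(build_dfba(m, g, sink = "B"))
  expect_equal(tr$status, "optimal")
  expect_equal(unname(tr$flux["r", ]), rep(2, g$M), tolerance = 1e-6)
  # sink grows linearly at rate 2
  expect_equal(unname(tr$conc["B", ]), 2 * g$node_times,
               tolerance = 1e-7)
})

test_that("minimal-fluctuation optimum is zero iff the state can stay put", {
  m <- small_model()
  g <- collocation_grid(0, 2, 2, 3)
  tr <- solve_dfba(build_mdfba(m, g, "conc"))
  expect_equal(tr$objective, 0, tolerance = 1e-8)
  expect_equal(max(abs(tr$conc - m$metabolites$x0)), 0, tolerance = 1e-5)
  # forcing the state away from x0 makes the optimum strictly positive
  cb <- dynfba:::conc_bounds_at(m, g$M)
  cb$lower["A", g$M] <- 2.5   # A must rise by the final node
  tr2 <- solve_dfba(build_mdfba(m, g, "conc", x_lower = cb$lower,
                                x_upper = cb$upper))
  expect_gt(tr2$objective, 1e-4)
  expect_gte(tr2$conc["A", g$M], 2.5 - 1e-7)
})

test_that("vacuous on/off thresholds admit an all-zero indicator optimum", {
  m <- small_model()
  g <- collocation_grid(0, 2, 1, 3)
  # gamma large enough that any feasible move stays inside the band
  th <- threshold_params(gamma_x = 50, gamma_v = 50, eps_x = 50,
                         eps_v = 50)
  tr <- solve_dfba(build_rdfba(m, g, "both", relaxed = FALSE,
                               thresholds = th))
  expect_equal(tr$objective, 0, tolerance = 1e-9)
})

test_that("solving is deterministic: same program and seed, same bits", {
  m <- small_model()
  g <- collocation_grid(0, 2, 2, 3)
  cb <- dynfba:::conc_bounds_at(m, g$M)
  cb$lower["A", g$M] <- 2.2
  p <- build_rdfba(m, g, "conc", relaxed = TRUE, x_lower = cb$lower,
                   x_upper = cb$upper)
  a <- solve_dfba(p, seed = 7, multistart = 3)
  b <- solve_dfba(p, seed = 7, multistart = 3)
  expect_identical(a$conc, b$conc)
  expect_identical(a$flux, b$flux)
  expect_identical(a$objective, b$objective)
})

test_that("programs print a readable listing", {
  p <- build_rdfba(calvin_model(), collocation_grid(0, 10, 5, 5), "conc",
                   relaxed = FALSE)
  out <- capture.output(print(p))
  expect_true(any(grepl("rdfba_minlp", out)))
  expect_true(any(grepl("gamma_x=0.4", out)))
  expect_true(any(grepl("binary", out)))
})
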