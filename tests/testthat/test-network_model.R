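test_that("Calvin fixture reproduces the published stoichiometry", {
  m <- calvin_model()
  expect_equal(m$N, 6)
  expect_equal(m$F, 7)
  S <- stoich_matrix(m)
  expect_equal(S["PGA", "v1"], 2)
  expect_equal(S["RuBP", "v1"], -1)
  expect_equal(S["Ru5P", "v4"], 0.6)
  expect_equal(unname(S[, "v1"]),
               c(0, -1, 2, 0, 0, 0))  # Ru5P RuBP PGA DPGA GAP Sink
  expect_equal(sum(S != 0), 14)  # two entries per reaction
  vmax <- unlist(m$reactions$v_max)
  expect_equal(unname(vmax), c(3.78, 11.75, 5.04, 3.05, 8, 3, 0.1))
  expect_equal(m$metabolites$x0, c(1, 2, 2.4, 1, 1, 1))
  # every reaction is irreversible
  expect_true(all(unlist(m$reactions$v_min) == 0))
})

test_that("carbon bookkeeping: only carboxylation fixes external carbon", {
  # carbon weights of (Ru5P, RuBP, PGA, DPGA, GAP, Sink); CO2 is outside
  # the simplified scheme, so c'S picks out v1 alone
  S <- stoich_matrix(calvin_model())
  cw <- c(5, 5, 3, 3, 3, 3)
  expect_equal(unname(as.vector(cw %*% S)), c(1, 0, 0, 0, 0, 0, 0))
})

test_that("fixtures are mass-connected: producers and consumers exist", {
  for (m in list(calvin_model(), carbohydrate_model("wild"))) {
    S <- stoich_matrix(m)
    sink <- grep("sink", m$metabolites$id, ignore.case = TRUE)
    for (i in seq_len(m$N)) {
      expect_true(any(S[i, ] > 0), info = rownames(S)[i])  # produced
      if (!i %in% sink) {
        expect_true(any(S[i, ] < 0), info = rownames(S)[i])  # consumed
      }
    }
    expect_true(all(S[sink, ] >= 0))  # the sink is never consumed
  }
})

test_that("carbohydrate fixture honours genotype and light phase", {
  wt <- carbohydrate_model("wild")
  expect_equal(wt$F, 7)
  inv <- carbohydrate_model("inv4")
  k <- match("invertase", inv$reactions$id)
  tgrid <- seq(0, 24, by = 0.5)
  expect_true(all(bound_at(dynfba:::reaction_bound(inv$reactions$v_max, k),
                           tgrid) == 0))
  expect_true(any(bound_at(dynfba:::reaction_bound(wt$reactions$v_max, k),
                           tgrid) > 0))
  kp <- match("photo", wt$reactions$id)
  photo <- dynfba:::reaction_bound(wt$reactions$v_max, kp)
  expect_gt(bound_at(photo, 8), 0)    # light phase
  expect_equal(bound_at(photo, 20), 0)  # hour 20 is dark
  expect_error(carbohydrate_model("unknown"))
})

test_that("model validation rejects malformed inputs with useful messages", {
  mets <- tibble::tibble(id = c("A", "B"), x0 = c(1, 1))
  expect_error(
    stoich_model(mets, tibble::tibble(id = character(), equation = character(),
                                      v_max = numeric())),
    "no reactions")
  expect_error(
    stoich_model(mets, tibble::tibble(id = "r1", equation = "A -> X",
                                      v_max = 1)),
    "X")
  expect_error(
    stoich_model(mets, tibble::tibble(id = "r1", equation = "A -> B",
                                      v_min = 2, v_max = 1)),
    "v_min > v_max")
  expect_error(
    stoich_model(tibble::tibble(id = c("A", "B"), x0 = c(1, 1),
                                x_max = Inf),
                 tibble::tibble(id = "r1", equation = "A -> B", v_max = 1)),
    "finite")
  expect_error(
    stoich_model(tibble::tibble(id = c("A", "A"), x0 = c(1, 1)),
                 tibble::tibble(id = "r1", equation = "A -> A 2",
                                v_max = 1)),
    "unique")
})

test_that("equation parsing handles coefficients, sources and sinks", {
  st <- dynfba:::parse_equation("A + 0.6 B -> C")
  expect_equal(st[["A"]], -1)
  expect_equal(st[["B"]], -0.6)
  expect_equal(st[["C"]], 1)
  st2 <- dynfba:::parse_equation("-> SugarP")
  expect_equal(st2[["SugarP"]], 1)
  expect_error(dynfba:::parse_equation("A + B"), class = "dynfba_parse_error")
  # one-reaction model A -> B gives the expected column
  m <- stoich_model(tibble::tibble(id = c("A", "B"), x0 = c(1, 0)),
                    tibble::tibble(id = "r", equation = "A -> B",
                                   v_max = 2))
  expect_equal(unname(stoich_matrix(m)[, 1]), c(-1, 1))
})
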