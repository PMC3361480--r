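make_traj <- function(times, conc, flux, method = "x") {
  dynfba:::new_trajectory(method, NULL, times,
                          x0 = conc[, 1], conc = conc, flux = flux,
                          starts = NULL, objective = NA_real_,
                          status = "optimal")
}

test_that("rss matches hand sums and a loop oracle on random input", {
  expect_equal(rss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rss(c(1, 2), c(0, 0)), 5)
  expect_error(rss(1:3, 1:2), class = "dynfba_eval_error")
  expect_error(rss(numeric(0), numeric(0)), class = "dynfba_eval_error")
  rng <- lcg <- local({
    state <- 42
    function(n) {
      out <- numeric(n)
      for (i in seq_len(n)) {
        state <<- (state * 48271) %% 2147483647
        out[i] <- state / 2147483647
      }
      out
    }
  })
  for (case in 1:1000) {
    y <- rng(25) * 10 - 5
    f <- rng(25) * 10 - 5
    expect_equal(rss(y, f), oracle_rss(y, f), tolerance = 1e-13)
  }
})

test_that("rss shift invariance and quadratic scaling hold", {
  y <- c(0.3, 1.7, 2.2, -0.5)
  f <- c(1.1, 1.5, 2.0, 0.0)
  expect_equal(rss(y + 3, f + 3), rss(y, f))
  expect_equal(rss(2.5 * y, 2.5 * f), 2.5^2 * rss(y, f))
})

test_that("Kendall tau-b matches exhaustive pair counting, ties included", {
  times <- 1:4
  conc <- rbind(c(1, 2, 3, 4), c(2, 1, 4, 3), c(5, 5, 5, 5))
  flux <- rbind(c(0.1, 0.4, 0.2, 0.3), c(1, 1, 2, 2))
  rownames(conc) <- paste0("m", 1:3); rownames(flux) <- paste0("r", 1:2)
  ref <- make_traj(times, conc, flux)
  # identical trajectories correlate perfectly at every node
  expect_equal(kendall_tau_timecourse(ref, ref)$tau, rep(1, 4))
  # rank reversal without ties gives -1
  conc2 <- -conc; flux2 <- -flux
  rev <- make_traj(times, conc2, flux2)
  tt <- kendall_tau_timecourse(ref, rev)$tau
  expect_equal(tt, rep(-1, 4))
  # 13-entry state vectors with ties: brute-force concordance counting
  rng <- local({
    state <- 99
    function(n) {
      out <- numeric(n)
      for (i in seq_len(n)) {
        state <<- (state * 48271) %% 2147483647
        out[i] <- state / 2147483647
      }
      out
    }
  })
  n_cases <- 1000
  A <- matrix(round(rng(13 * n_cases) * 6) / 2, 13)  # coarse => ties
  B <- matrix(round(rng(13 * n_cases) * 6) / 2, 13)
  ref13 <- make_traj(seq_len(n_cases), A[1:7, ], A[8:13, ])
  prd13 <- make_traj(seq_len(n_cases), B[1:7, ], B[8:13, ])
  got <- kendall_tau_timecourse(ref13, prd13)$tau
  want <- vapply(seq_len(n_cases),
                 function(j) oracle_tau_b(A[, j], B[, j]), numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(abs(got[!is.na(got)]) <= 1))
})

test_that("tau is invariant under joint strictly monotone transforms", {
  times <- c(0.5, 1.5)
  conc <- rbind(c(1, 2), c(3, 0.5)); flux <- rbind(c(2, 2))
  rownames(conc) <- c("a", "b"); rownames(flux) <- "r"
  ref <- make_traj(times, conc, flux)
  pred <- make_traj(times, conc[2:1, , drop = FALSE] + 1,
                    flux + 0.3)
  rownames(pred$conc) <- c("a", "b")
  base <- kendall_tau_timecourse(ref, pred)$tau
  mono <- function(x) exp(2 * x) + 1
  ref2 <- make_traj(times, mono(conc), mono(flux))
  pred2 <- make_traj(times, mono(pred$conc), mono(pred$flux))
  expect_equal(kendall_tau_timecourse(ref2, pred2)$tau, base,
               tolerance = 1e-12)
})

test_that("comparison reports rank methods by separate conc/flux totals", {
  times <- 1:3
  conc_ref <- rbind(c(1, 2, 3), c(2, 2, 2))
  flux_ref <- rbind(c(1, 1, 1))
  rownames(conc_ref) <- c("A", "B"); rownames(flux_ref) <- "r"
  ref <- make_traj(times, conc_ref, flux_ref, "ref")
  perfect <- make_traj(times, conc_ref, flux_ref, "perfect")
  off1 <- make_traj(times, conc_ref + 1, flux_ref + 2, "off1")
  off2 <- make_traj(times, conc_ref + 2, flux_ref + 1, "off2")
  cmp <- compare_methods(list(perfect = perfect, off1 = off1,
                              off2 = off2), ref)
  s <- glance(cmp)
  expect_equal(s$method[s$rank_conc == 1], "perfect")
  expect_equal(s$rss_conc[s$method == "perfect"], 0)
  # hand-computed totals: off1 adds 1 to 2x3 conc entries -> 6;
  # off2 adds 2 -> 24; flux swaps
  expect_equal(s$rss_conc[s$method == "off1"], 6)
  expect_equal(s$rss_conc[s$method == "off2"], 24)
  expect_equal(s$rss_flux[s$method == "off1"], 12)
  expect_equal(s$rss_flux[s$method == "off2"], 3)
  expect_equal(s$rank_flux[s$method == "off2"] <
                 s$rank_flux[s$method == "off1"], TRUE)
  # per-element dominance carries to the totals
  expect_true(all(tidy(cmp)$rss[tidy(cmp)$method == "off1" &
                                  tidy(cmp)$kind == "metabolite"] <
                    tidy(cmp)$rss[tidy(cmp)$method == "off2" &
                                    tidy(cmp)$kind == "metabolite"]))
  expect_error(compare_methods(list(make_traj(1:2, conc_ref[, 1:2],
                                              flux_ref[, 1:2])), ref),
               class = "dynfba_eval_error")
})

test_that("comparison output files are written in the documented schema", {
  times <- 1:3
  conc <- rbind(A = c(1, 2, 3)); flux <- rbind(r = c(1, 1, 2))
  ref <- make_traj(times, conc, flux, "ref")
  cmp <- compare_methods(list(m1 = make_traj(times, conc + 1, flux)), ref)
  dir <- withr::local_tempdir()
  write_comparison(cmp, dir)
  expect_true(all(file.exists(file.path(dir, c("rss.csv", "tau.csv",
                                               "summary.json")))))
  rss_back <- readr::read_csv(file.path(dir, "rss.csv"),
                              show_col_types = FALSE)
  expect_equal(names(rss_back), c("method", "kind", "id", "rss"))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$summary[[1]]$method, "m1")
})
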