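adult_runs <- local({
  p <- model_params()
  list(p = p,
       lo = simulate_homeostasis(p, init_resting = 0.01e11, t_end = 1000),
       hi = simulate_homeostasis(p, init_resting = 2e11, t_end = 1000))
})

test_that("both canonical starts converge to the same set point just above 1e11", {
  lo <- adult_runs$lo
  hi <- adult_runs$hi
  Nlo <- lo$N_cells[nrow(lo)]
  Nhi <- hi$N_cells[nrow(hi)]
  expect_gt(Nlo, 1e11)
  expect_lt(Nlo, 1.2e11)
  expect_lt(abs(Nhi / Nlo - 1), 0.001)
  # and both agree with the root-found equilibrium
  eq <- steady_state(adult_runs$p)
  expect_lt(abs(Nlo / eq$N - 1), 0.001)
})

test_that("lymphopenic recovery reaches the set point within 300 days", {
  ct <- convergence_time(adult_runs$lo)
  expect_lte(ct, 300)
  expect_gte(ct, 100)
  expect_equal(convergence_time(adult_runs$hi) <= 300, TRUE)
  # starting at the fixed point the band is entered immediately
  eq <- steady_state(adult_runs$p)
  at_eq <- simulate_homeostasis(adult_runs$p, eq$X, eq$Y, t_end = 1000)
  expect_equal(convergence_time(at_eq), 0)
  # nested bands: tightening the band cannot shorten the reported time
  expect_gte(convergence_time(adult_runs$lo, band = 0.025),
             convergence_time(adult_runs$lo, band = 0.05))
})

test_that("dividing fraction transients match the homeostatic picture", {
  lo <- adult_runs$lo
  hi <- adult_runs$hi
  # lymphopenic burst peaks near 1.3%
  expect_gt(peak_ratio(lo), 0.012)
  expect_lt(peak_ratio(lo), 0.014)
  # quasi-steady fast-transient check: peak ~ lambda(N0)/r
  qs <- division_rate(0.01e11, adult_runs$p) / adult_runs$p$r
  expect_lt(abs(peak_ratio(lo) / qs - 1), 0.1)
  # excess start shoulders near 0.2% after the fast transient...
  expect_gt(ratio_at(hi, 5), 0.0018)
  expect_lt(ratio_at(hi, 5), 0.0023)
  # ...then climbs slowly toward equilibrium
  expect_gt(ratio_at(hi, 500), ratio_at(hi, 5))
  # terminal fraction brackets the observed ~0.4-0.5% cycling cells
  expect_gt(lo$ratio[nrow(lo)], 0.004)
  expect_lt(lo$ratio[nrow(lo)], 0.0055)
})

test_that("trajectories are nonnegative and time grids strictly increase", {
  set.seed(5)
  for (i in 1:5) {
    p <- model_params(theta = 10^runif(1, 7, 9),
                      lambda0 = 10^runif(1, -2, -0.5),
                      r = 10^runif(1, -0.5, 0.8))
    tr <- simulate_homeostasis(p, init_resting = 10^runif(1, 8, 11.5),
                               init_dividing = 10^runif(1, 0, 8),
                               t_end = 200)
    expect_true(all(tr$X_cells >= 0))
    expect_true(all(tr$Y_cells >= 0))
    expect_true(all(diff(tr$time_days) > 0))
    expect_equal(tr$N_cells, tr$X_cells + tr$Y_cells)
  }
})

test_that("solution is solver-tolerance independent to 0.01%", {
  p <- model_params()
  a <- simulate_homeostasis(p, 0.01e11, t_end = 500)
  b <- simulate_homeostasis(p, 0.01e11, t_end = 500,
                            rtol = 5e-9, atol = 5e-13)
  expect_lt(max(abs(a$N_cells / b$N_cells - 1)), 1e-4)
})

test_that("interdivision time at the adult set point is in the reported range", {
  eq <- steady_state(model_params())
  idt <- interdivision_time(eq$N, eq$params)
  expect_gt(idt, 50)
  expect_lt(idt, 60)
})

test_that("non-converged trajectories and undefined ratios are reported", {
  p <- model_params()
  short <- simulate_homeostasis(p, 0.01e11, t_end = 40)
  expect_error(convergence_time(short), "not converged")
  # a trajectory that passes through X = 0 has no defined ratio
  tr <- simulate_homeostasis(p, 0.01e11, t_end = 10)
  tr$X_cells[1] <- 0
  expect_error(peak_ratio(tr), "X = 0")
  expect_error(ratio_at(tr, 1e5), "outside")
})
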