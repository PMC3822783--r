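test_that("default parameters reproduce the published adult values in model units", {
  p <- model_params()
  cu <- p$cell_unit
  expect_identical(cu, 1e11)
  expect_equal(p$theta / cu, 0.003)
  expect_equal(p$lambda0, 0.055)
  expect_equal(p$epsilon / cu, 1)
  expect_equal(p$delta0, 0.02)
  expect_equal(p$rho / cu, 100)
  expect_equal(p$r, 4)
  expect_equal(p$mu_prime * cu, 15)
})

test_that("parameter validation rejects non-positive and missing fields", {
  expect_error(model_params(theta = 0), "positive")
  expect_error(model_params(r = -1), "positive")
  expect_error(update_params(model_params(), nonsense = 1), "unknown")
  expect_s3_class(update_params(model_params(), r = 0.5), "model_params")
  expect_equal(update_params(model_params(), r = 0.5)$r, 0.5)
})

test_that("division, death and AICD rates match their closed forms", {
  p <- model_params()
  # frozen values evaluated from the closed forms by hand
  expect_equal(division_rate(0, p), 0.055)
  expect_equal(division_rate(1e11, p), 0.0202333693, tolerance = 1e-8)
  expect_equal(division_rate(2e11, p), 0.0074434406, tolerance = 1e-8)
  expect_equal(resting_death_rate(0, p), 0.02)
  expect_equal(resting_death_rate(100 * 1e11, p), 0.0543656366, tolerance = 1e-8)
  expect_equal(resting_death_rate(1.1e11, p), 0.0202212144, tolerance = 1e-8)
  expect_equal(dividing_death_rate(0, p), 0)
  expect_equal(dividing_death_rate(5e8, p), 0.075)
  # linearity of the AICD rate in Y
  expect_equal(dividing_death_rate(2 * 7e8, p), 2 * dividing_death_rate(7e8, p))
})

test_that("rates agree with an independent scalar oracle to 1e-12 relative", {
  p <- model_params()
  set.seed(11)
  N <- c(0, 10^runif(40, 6, 12.5))
  expect_rel_equal(division_rate(N[-1], p),
                   oracle_lambda(N[-1], p$lambda0, p$epsilon), 1e-12)
  expect_rel_equal(resting_death_rate(N[-1], p),
                   oracle_delta(N[-1], p$delta0, p$rho), 1e-12)
  for (i in 1:20) {
    X <- 10^runif(1, 6, 11.5)
    Y <- 10^runif(1, 4, 9.5)
    got <- model_rhs(X, Y, p)
    want <- oracle_rhs(X, Y, p$theta, p)
    expect_rel_equal(c(got$dX, got$dY), want, 1e-12)
  }
})

test_that("lambda decreases and delta increases strictly with total cell number", {
  p <- model_params()
  set.seed(7)
  for (i in 1:50) {
    ab <- sort(10^runif(2, 6, 13))
    expect_gt(division_rate(ab[1], p), division_rate(ab[2], p))
    expect_lt(resting_death_rate(ab[1], p), resting_death_rate(ab[2], p))
  }
})

test_that("negative cell numbers are rejected as domain errors", {
  p <- model_params()
  expect_error(division_rate(-1, p), "non-negative")
  expect_error(resting_death_rate(-1, p), "non-negative")
  expect_error(dividing_death_rate(-1, p), "non-negative")
  expect_error(model_rhs(-1, 0, p), "non-negative")
  expect_error(model_rhs(0, -1, p), "non-negative")
})

test_that("rhs matches hand arithmetic and cannot push the flow negative", {
  p <- model_params()
  # empty compartments: pure thymic influx
  d0 <- model_rhs(0, 0, p)
  expect_equal(d0$dX, 3e8)
  expect_equal(d0$dY, 0)
  # X = 1e11, Y = 0: hand arithmetic through the closed forms
  d1 <- model_rhs(1e11, 0, p)
  expect_equal(d1$dX, 3e8 - (0.0202333693 + 0.0202010033) * 1e11,
               tolerance = 1e-7)
  expect_equal(d1$dY, 0.0202333693 * 1e11, tolerance = 1e-7)
  # boundary of the nonnegative quadrant: dX >= theta at X = 0, dY >= 0 at Y = 0
  set.seed(3)
  for (i in 1:25) {
    Y <- 10^runif(1, 2, 10)
    X <- 10^runif(1, 2, 12)
    expect_gte(model_rhs(0, Y, p)$dX, p$theta)
    expect_gte(model_rhs(X, 0, p)$dY, 0)
  }
})

test_that("interdivision time is the reciprocal division rate", {
  p <- model_params()
  expect_equal(interdivision_time(0, p), 1 / 0.055)
  expect_equal(interdivision_time(1e11, p), 1 / division_rate(1e11, p))
  # more division resource at fixed N -> shorter wait
  p2 <- update_params(p, epsilon = 2 * p$epsilon)
  expect_lt(interdivision_time(1e11, p2), interdivision_time(1e11, p))
})
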