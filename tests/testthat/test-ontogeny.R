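test_that("thymic ontogeny curve hits its three anchors exactly", {
  cfg <- ontogeny_config()
  expect_equal(theta_of_age(0, cfg), 4e8)
  expect_equal(theta_of_age(1, cfg), 2e9)
  expect_equal(theta_of_age(20, cfg), 3e8)
  # peak is the global maximum; rises before, falls after
  ages <- seq(0, 20, by = 0.01)
  th <- theta_of_age(ages, cfg)
  expect_equal(max(th), 2e9)
  expect_equal(ages[which.max(th)], 1)
  expect_true(all(diff(th[ages <= 1]) >= 0))
  expect_true(all(diff(th[ages >= 1 & ages <= 20]) <= 0))
  # continuity across the peak join
  expect_lt(abs(theta_of_age(1 - 1e-9, cfg) / theta_of_age(1 + 1e-9, cfg) - 1),
            1e-6)
  # constant at the adult value beyond 20 years
  expect_equal(theta_of_age(35, cfg), 3e8)
  expect_error(theta_of_age(-0.1, cfg), "non-negative")
})

test_that("blood volume interpolates its table linearly and refuses extrapolation", {
  cfg <- ontogeny_config()
  tb <- cfg$blood_volume_table
  expect_equal(blood_volume(tb$age_years, cfg), tb$volume_litres)
  mid <- (tb$age_years[3] + tb$age_years[4]) / 2
  expect_equal(blood_volume(mid, cfg),
               (tb$volume_litres[3] + tb$volume_litres[4]) / 2)
  expect_equal(blood_volume(20, cfg), 5)
  expect_error(blood_volume(21, cfg), "table range")
  expect_error(blood_volume(-1, cfg), "table range")
})

test_that("concentration conversion is the blood-fraction-scaled density", {
  cfg <- ontogeny_config()
  expect_equal(cd4_concentration(0, 1, cfg), 0)
  # adult: 2% of 1.1e11 cells in 5 litres = 440 cells/ul
  expect_equal(cd4_concentration(1.1e11, 20, cfg), 440)
  cfg2 <- ontogeny_config(blood_fraction = 0.04)
  expect_equal(cd4_concentration(1.1e11, 20, cfg2),
               2 * cd4_concentration(1.1e11, 20, cfg))
})

test_that("ontogeny configuration is validated", {
  expect_error(ontogeny_config(theta_peak = 1e8), "global maximum")
  expect_error(ontogeny_config(blood_fraction = 0), "blood_fraction")
  bad <- data.frame(age_years = c(0, 1), volume_litres = c(1, 0.5))
  expect_error(ontogeny_config(blood_volume_table = bad), "increasing")
})

test_that("pediatric concentration rises after birth then slowly declines", {
  ped <- simulate_childhood(model_params(), ontogeny_config(), age_end = 3)
  conc <- ped$concentration_cells_per_ul
  i_peak <- which.max(conc)
  expect_gt(i_peak, 2)                    # interior peak...
  expect_lt(i_peak, nrow(ped) - 2)        # ...not at either end
  expect_gt(conc[i_peak], conc[1])
  expect_gt(conc[i_peak], conc[nrow(ped)])
  expect_lt(ped$age_years[i_peak], 1.5)   # peak within infancy
  # whole-body numbers rise steeply over the first year and end higher
  N <- ped$N_total_cells
  expect_true(all(diff(N[ped$age_years <= 1]) > 0))
  expect_gt(N[nrow(ped)], N[1])
})

test_that("with constant adult input the pediatric run reduces to the adult set point", {
  flat <- ontogeny_config(
    theta_birth = 3e8, theta_peak = 3e8, theta_adult = 3e8,
    blood_volume_table = data.frame(age_years = c(0, 20),
                                    volume_litres = c(5, 5 + 1e-9))
  )
  ped <- simulate_childhood(model_params(), flat, age_end = 5, age_step = 0.25)
  eq <- steady_state(model_params())
  expect_lt(abs(ped$N_total_cells[nrow(ped)] / eq$N - 1), 0.005)
  expect_lt(abs(ped$concentration_cells_per_ul[nrow(ped)] /
                  cd4_concentration(eq$N, 20, flat) - 1), 0.005)
})

test_that("results are invariant to the internal cell-unit scaling", {
  cfg <- ontogeny_config()
  # algebraic pipeline: exact to near machine precision
  p1 <- model_params()
  p2 <- model_params(cell_unit = 1e10)
  expect_rel_equal(division_rate(1.3e11, p2), division_rate(1.3e11, p1), 1e-12)
  expect_rel_equal(steady_state(p2)$N, steady_state(p1)$N, 1e-8)
  # integrated pipeline: agreement at the solver-tolerance scale
  a <- simulate_childhood(p1, cfg, age_end = 2, age_step = 0.25)
  b <- simulate_childhood(p2, cfg, age_end = 2, age_step = 0.25)
  expect_lt(max(abs(b$concentration_cells_per_ul[-1] /
                      a$concentration_cells_per_ul[-1] - 1)), 1e-5)
})
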