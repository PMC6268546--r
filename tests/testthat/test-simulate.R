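test_that("timecourse honours lag, equilibrium and the ODE oracle", {
  g <- pampa_geometry()
  # no flux without permeability
  tc0 <- simulate_well_timecourse(c(0, 1e4, 2.5e4), Pe = 0, R = 0.3, g)
  expect_equal(tc0$C_A, rep(0, 3))

  # before/at the lag boundary the acceptor is empty and the donor holds
  # the unretained fraction
  tc <- simulate_well_timecourse(c(0, g$tau_lag), Pe = 2e-5, R = 0.5, g)
  expect_equal(tc$C_A, c(0, 0))
  expect_equal(tc$C_D, rep(0.5 * g$C_D0_nominal, 2))

  # t -> infinity approaches the equilibrium partition (1-R) V_D/(V_A+V_D)
  tcl <- simulate_well_timecourse(1e9, Pe = 2e-5, R = 0.5, g)
  expect_equal(tcl$C_A / g$C_D0_nominal, 0.5 * 0.3 / 0.7, tolerance = 1e-12)

  # numerical integration of the flux ODE lands on the analytic endpoint
  for (Pe in c(1e-6, 2.2103e-5)) {
    end <- simulate_well_timecourse(g$t_incubation, Pe, 0.25, g)
    expect_equal(end$C_A, ode_acceptor(Pe, 0.25, g, g$t_incubation),
                 tolerance = 1e-9)
  }

  # the inverse of the closed-form permeability example: this Pe yields
  # exactly a quarter of the dose in the acceptor of an equal-volume well
  ge <- geom_equal()
  end <- simulate_well_timecourse(ge$t_incubation, 2.2103e-5, 0, ge)
  expect_equal(end$C_A / ge$C_D0_nominal, 0.25, tolerance = 1e-4)

  expect_error(simulate_well_timecourse(-1, 1e-5, 0, g), "t must")
  expect_error(simulate_well_timecourse(0, 1e-5, 1, g), "\\[0, 1\\)")
})

test_that("mass is conserved exactly at all times (noise-free)", {
  g <- pampa_geometry()
  set.seed(5)
  for (i in 1:20) {
    Pe <- 10^runif(1, -7, -4); R <- runif(1, 0, 0.95)
    t <- runif(5, 0, g$t_incubation)
    tc <- simulate_well_timecourse(t, Pe, R, g)
    total <- tc$C_D * g$V_D + tc$C_A * g$V_A +
      R * g$C_D0_nominal * g$V_D
    expect_equal(total, rep(g$C_D0_nominal * g$V_D, 5), tolerance = 1e-14)
  }
})

test_that("acceptor accumulation is monotone in time and Pe, below C_eq", {
  g <- pampa_geometry()
  t <- seq(0, g$t_incubation, length.out = 50)
  tc <- simulate_well_timecourse(t, Pe = 3e-5, R = 0.2, g)
  expect_true(all(diff(tc$C_A) >= 0))
  C_eq <- 0.8 * g$C_D0_nominal * g$V_D / (g$V_A + g$V_D)
  expect_true(all(tc$C_A < C_eq))
  pe_grid <- 10^seq(-7, -4, length.out = 20)
  ca <- vapply(pe_grid, function(pe)
    simulate_well_timecourse(g$t_incubation, pe, 0.2, g)$C_A, numeric(1))
  expect_true(all(diff(ca) > 0))
})

test_that("plate simulation is seed-reproducible with the right shape", {
  ids <- sprintf("c%02d", 1:26)
  p1 <- simulate_plate(ids, Pe = 2e-5, R = 0.4, seed = 123)
  p2 <- simulate_plate(ids, Pe = 2e-5, R = 0.4, seed = 123)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 78L)  # 26 compounds x 3 replicates
  p3 <- simulate_plate(ids, Pe = 2e-5, R = 0.4, seed = 124)
  expect_false(identical(p1, p3))
  expect_error(simulate_plate(c("a", "a"), 1e-5, 0), "duplicate")
})

test_that("empirical area CV converges to the requested noise level", {
  plate <- simulate_plate(sprintf("c%04d", 1:2000), Pe = 2e-5, R = 0.4,
                          noise_cv = 0.02, n_replicates = 1L, seed = 99)
  cv <- sd(plate$area_donor_t) / mean(plate$area_donor_t)
  expect_equal(cv, 0.02, tolerance = 0.1)
  # noise-free plates are exact
  p0 <- simulate_plate("a", Pe = 2e-5, R = 0.4, noise_cv = 0, seed = 1)
  expect_equal(unique(p0$area_t0), pampa_geometry()$C_D0_nominal)
})
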