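test_that("Lame parameters follow the printed formulas", {
  lp <- lame_parameters(13, 95, 20, 0.49)
  expect_equal(unname(lp["mu_lame"]), 95 * 13 / (2 * 20 * 1.49),
               tolerance = 1e-12)
  expect_equal(unname(lp["mu_lame"]), 20.7215, tolerance = 1e-4)
  expect_equal(unname(lp["lambda_lame"]),
               0.49 * 95 * 13 / (1.49 * 0.02 * 20), tolerance = 1e-12)
  expect_equal(unname(lp["lambda_lame"]), 1015.352, tolerance = 1e-4)
  # nu -> 0 kills lambda
  expect_lt(lame_parameters(13, 20, 20, 1e-9)["lambda_lame"], 1e-6)
  expect_error(lame_parameters(13, 95, 20, 0.5), "incompressible")
  expect_error(lame_parameters(-1, 95, 20, 0.4), "> 0")
})

test_that("strain energy vanishes at the reference state and grows in I1", {
  mat <- wall_material()
  expect_identical(strain_energy(mat, 3, 1), 0)
  # hand evaluation with mu = 2, lambda = 5 at I1 = 4, J = 1
  expect_equal(strain_energy(list(mu_lame = 2, lambda_lame = 5), 4, 1), 1)
  W <- strain_energy(mat, c(3, 3.5, 4, 6), 1)
  expect_true(all(diff(W) > 0))
  # non-negative near the reference for positive Lame parameters
  expect_true(all(strain_energy(mat, 3, c(0.95, 1, 1.05)) >= 0))
  expect_error(strain_energy(mat, 3, 0), "positive")
})

test_that("mucus viscosity is the printed affine law", {
  mu <- mucus_properties()
  expect_identical(mucus_viscosity(mu, 0), 0.98)
  expect_identical(mucus_viscosity(mu, 1), 1.00)
  expect_identical(mucus_viscosity(mu, 50), 1.98)
  expect_equal(diff(mucus_viscosity(mu, c(10, 11))), 0.02)
  expect_error(mucus_viscosity(mu, -1), "non-negative")
})

test_that("wall displacement responds linearly to forcing and is 40 s periodic", {
  tube <- build_tube("30s")
  mat <- wall_material(L_ref = tube$total_length)
  waves <- list(peristalsis_wave(direction = "pro_ovary"),
                peristalsis_wave(direction = "pro_uterus", origin_s = 95))
  # no forcing, no displacement
  w0 <- lapply(waves, function(w) { w$amplitude_p <- 0; w })
  expect_equal(wall_displacement(tube, mat, w0, seq(0, 95, 5), 13),
               rep(0, 20))
  # periodic with the contraction period 60 / 1.5 = 40 s
  s <- c(10, 40, 70)
  for (tt in c(0, 7.3, 21)) {
    expect_equal(wall_displacement(tube, mat, waves, s, tt),
                 wall_displacement(tube, mat, waves, s, tt + 40),
                 tolerance = 1e-10)
  }
  # doubling mu_lame halves the amplitude
  mat2 <- mat; mat2$mu_lame <- 2 * mat$mu_lame
  d1 <- wall_displacement(tube, mat, waves, s, 11)
  d2 <- wall_displacement(tube, mat2, waves, s, 11)
  expect_equal(d1, 2 * d2, tolerance = 1e-12)
  # never exceeds 90% of the resting radius even under huge forcing
  big <- lapply(waves, function(w) { w$amplitude_p <- 1e5; w })
  r0 <- local_radius(tube, s, 0, folds = FALSE)
  expect_true(all(wall_displacement(tube, mat, big, s, 3) <= 0.9 * r0 + 1e-12))
})

test_that("flow vanishes without drive and cilia slip is pro-uterus at the wall", {
  tube <- build_tube("20s")
  quiet <- flow_model(
    tube,
    waves = list(peristalsis_wave(amplitude_p = 0)),
    cilia = cilia_field(density = 0))
  expect_equal(flow_velocity(quiet, c(5, 50, 100), 0.5, 12), rep(0, 3))

  cil_only <- flow_model(tube,
                         waves = list(peristalsis_wave(amplitude_p = 0)),
                         cilia = cilia_field(density = tube$cilia_density))
  u_wall <- flow_velocity(cil_only, seq(2, 100, 7), 1, 5)
  expect_true(all(u_wall < 0))           # toward the uterus
  expect_equal(flow_velocity(cil_only, 50, 0.6, 5), 0)  # decays to core
  expect_equal(flow_velocity(cil_only, 50, 0.3, 5), 0)
  expect_error(flow_velocity(cil_only, 50, 1.2, 0), "r_frac")
})

test_that("ciliary slip decreases with age at fixed calibration", {
  slips <- vapply(c("20s", "30s", "40s"), function(a)
    cilia_slip_speed(cilia_field(density = build_tube(a)$cilia_density)),
    numeric(1))
  expect_true(all(diff(slips) < 0))
})

test_that("peristaltic flux conserves mass on the axial grid", {
  tube <- build_tube("20s")
  fl <- flow_model(tube)
  for (tt in c(3, 17, 31)) {
    st <- oviductsim:::.flow_grid_state(fl, tt)
    h <- diff(fl$s_grid[1:2])
    dQds <- diff(st$Q) / h
    # recompute dA/dt by central finite difference in time
    st_p <- oviductsim:::.flow_grid_state(fl, tt + 1e-3)
    st_m <- oviductsim:::.flow_grid_state(fl, tt - 1e-3)
    dAdt <- (st_p$A - st_m$A) / 2e-3
    dAdt_mid <- (dAdt[-1] + dAdt[-length(dAdt)]) / 2
    expect_lt(max(abs(dQds + dAdt_mid)), 1e-4 * max(abs(dAdt_mid)) + 1e-10)
  }
  # flux is s-continuous on the grid (no jumps across region boundaries)
  st <- oviductsim:::.flow_grid_state(fl, 9)
  expect_lt(max(abs(diff(st$Q))), 0.5)  # mm^3/s per grid cell, smooth
})

test_that("flow fields are 40 s periodic on static geometry", {
  tube <- build_tube("40s")
  fl <- flow_model(tube)
  s <- c(12, 44, 80); r <- c(0.2, 0.5, 0.9)
  expect_equal(flow_velocity(fl, s, r, 6), flow_velocity(fl, s, r, 46),
               tolerance = 1e-10)
  expect_equal(flow_flux(fl, s, 6), flow_flux(fl, s, 46), tolerance = 1e-10)
})
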