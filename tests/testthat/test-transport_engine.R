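test_that("initial positions respect the release regions and the seed", {
  tube <- build_tube("20s")
  ds <- simulation_design("sperm", n_agents = 400L, seed = 11)
  st <- init_positions(ds, tube)
  b <- region_bounds(tube, "intramural")
  expect_true(all(st$s >= b[1] & st$s <= b[2]))
  expect_true(all(st$r_frac >= 0 & st$r_frac <= 1))

  do <- simulation_design("oocyte", n_agents = 50L, seed = 11)
  sto <- init_positions(do, tube)
  bo <- region_bounds(tube, "infundibulum")
  expect_true(all(sto$s >= bo[1] & sto$s <= bo[2]))

  st2 <- init_positions(ds, tube)
  expect_identical(st$s, st2$s)
  expect_identical(st$theta, st2$theta)
})

test_that("a zero-duration run leaves every agent swimming", {
  d <- simulation_design("sperm", n_agents = 20L, duration = 0, seed = 3)
  r <- run_transport(d)
  expect_true(all(r$agents$status == "swimming"))
  expect_true(all(is.na(r$agents$t_final)))
})

test_that("identical seed and config give bitwise-identical outcomes", {
  d <- simulation_design("oocyte", n_agents = 40L, duration = 30, seed = 5,
                         age_group = "30s", with_endometriosis = TRUE)
  r1 <- run_transport(d)
  r2 <- run_transport(d)
  expect_identical(r1$agents, r2$agents)
  d2 <- simulation_design("oocyte", n_agents = 40L, duration = 30, seed = 6,
                          age_group = "30s", with_endometriosis = TRUE)
  expect_false(identical(run_transport(d2)$agents$final_s, r1$agents$final_s))
})

test_that("agents are conserved and terminal states absorb", {
  d <- simulation_design("sperm", n_agents = 300L, duration = 4, seed = 9,
                         age_group = "40s", with_endometriosis = TRUE)
  r <- run_transport(d)
  tab <- table(factor(r$agents$status,
                      levels = c("swimming", "stuck", "reached_goal")))
  expect_equal(sum(tab), 300L)
  # every terminal agent carries a finite absorption time within duration
  done <- r$agents$status != "swimming"
  expect_true(all(is.finite(r$agents$t_final[done])))
  expect_true(all(r$agents$t_final[done] <= 4 + 1e-9))
  # stuck agents record where they stuck
  expect_true(all(r$agents$stuck_at[r$agents$status == "stuck"] != "none"))
  expect_true(all(r$agents$stuck_at[r$agents$status != "stuck"] == "none"))
})

test_that("a lone sperm in quiet fluid swims monotonically pro-ovary", {
  tube <- build_tube("20s")
  p <- quiet_params()
  agent <- list(s = 5, r_frac = 0.3, theta = 1, mode = "normal",
                status = "swimming")
  s_seen <- numeric(0)
  for (i in 1:50) {
    agent <- step_sperm(agent, tube, params = p, t = i - 1)
    s_seen <- c(s_seen, agent$s)
  }
  expect_true(all(diff(c(5, s_seen)) > 0))
  expect_equal(agent$status, "swimming")
})

test_that("sperm hyperactivate on ampulla entry under the default trigger", {
  tube <- build_tube("20s")
  p <- quiet_params()
  amp <- region_bounds(tube, "ampulla")
  agent <- list(s = amp[1] - 0.01, r_frac = 0.3, theta = 0, mode = "normal",
                status = "swimming")
  agent <- step_sperm(agent, tube, params = p, t = 0)
  expect_equal(agent$mode, "hyperactivated")
})

test_that("an oocyte without flow never reaches the uterine cavity", {
  p <- quiet_params()
  d <- simulation_design("oocyte", n_agents = 3L, duration = 80, seed = 2)
  r <- run_transport(d, params = p)
  expect_true(all(r$agents$status == "swimming"))
  b <- region_bounds(build_tube("20s"), "infundibulum")
  expect_true(all(r$agents$final_s >= b[1]))  # never moved out
})

test_that("oocyte transport is axial with minimal lateral displacement", {
  d <- simulation_design("oocyte", n_agents = 5L, duration = 40, seed = 8,
                         record_trajectories = TRUE, trajectory_stride = 30L)
  r <- run_transport(d)
  tr <- r$trajectories
  expect_false(is.null(tr))
  for (id in unique(tr$id)) {
    path <- tr[tr$id == id, ]
    live <- path[path$status == 0, ]
    if (nrow(live) < 10) next
    axial_span <- diff(range(live$s))
    lateral_rms <- stats::sd(live$r_frac * 2)  # generous mm-scale bound
    expect_gt(axial_span, 20)
    expect_lt(lateral_rms, 0.5)
  }
})

test_that("nullified lesions reproduce the normal tube exactly (same seed)", {
  p <- default_params("20s")
  p$protrusion_frac <- 0
  p$sperm$h_lesion <- 0
  p$oocyte$h_lesion <- 0
  for (kind in c("sperm", "oocyte")) {
    dn <- simulation_design(kind, n_agents = 150L, duration = 20, seed = 21,
                            age_group = "20s", with_endometriosis = FALSE)
    de <- simulation_design(kind, n_agents = 150L, duration = 20, seed = 21,
                            age_group = "20s", with_endometriosis = TRUE)
    rn <- run_transport(dn, params = p)
    re <- run_transport(de, params = p)
    expect_identical(rn$agents$status, re$agents$status)
    expect_identical(rn$agents$final_s, re$agents$final_s)
    expect_identical(rn$agents$t_final, re$agents$t_final)
  }
})

test_that("reached fraction falls with age, lesion count and sticking", {
  pct <- function(kind, age, endo, n = 350L, params = default_params(age),
                  lesions = NULL) {
    d <- simulation_design(kind, n_agents = n, seed = 31, age_group = age,
                           with_endometriosis = endo)
    tube <- if (is.null(lesions)) NULL else
      build_tube(age, endo, lesion_count = lesions,
                 overrides = list(lesion_protrusion_frac =
                                    params$protrusion_frac))
    r <- run_transport(d, tube = tube, params = params)
    100 * mean(r$agents$status == "reached_goal")
  }
  # age monotonicity (large calibrated effect sizes; small-n slack 5 pp)
  p20 <- pct("sperm", "20s", FALSE)
  p30 <- pct("sperm", "30s", FALSE)
  p40 <- pct("sperm", "40s", FALSE)
  expect_gt(p20, p30 - 5); expect_gt(p30, p40 - 5)
  expect_gt(p20, p40 + 10)

  # sticking-probability monotonicity at fixed geometry
  base <- default_params("30s")
  hi <- base; hi$sperm$h_lesion <- 50 * base$sperm$h_lesion
  zero <- base; zero$sperm$h_lesion <- 0
  pz <- pct("sperm", "30s", TRUE, params = zero)
  pb <- pct("sperm", "30s", TRUE, params = base)
  ph <- pct("sperm", "30s", TRUE, params = hi)
  expect_gte(pz, pb - 3); expect_gt(pb, ph)

  # lesion-count monotonicity: 0 vs 10 lesions
  p0 <- pct("sperm", "20s", FALSE)
  p10 <- pct("sperm", "20s", TRUE, lesions = 10L)
  expect_gt(p0, p10 - 3)
})
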