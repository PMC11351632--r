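# Agent transport through the tube: sperm self-propel pro-ovary through the
# peristalsis-ciliary flow toward the ampullary fertilization site; oocytes
# are advected pro-uterus by the near-wall ciliary flow toward the uterine
# cavity. Agents evolve in the backbone frame (s, r_frac, theta); wall and
# lesion sticking are per-second hazards; stuck and reached_goal states are
# absorbing. All agents of a run advance together in a vectorised stepper
# with a single seeded RNG stream, so identical (seed, config) pairs give
# bitwise-identical outcomes.

#' Simulation design
#'
#' The canonical designs track 10,000 sperm or 100 single-oocyte runs for
#' 80 simulated hours (one design per age group, with and without
#' endometriosis). All counts and durations are scalable.
#'
#' @param kind `"sperm"` or `"oocyte"`.
#' @param n_agents Agents per replicate (canonical: 10,000 sperm or 100
#'   oocyte runs).
#' @param n_replicates Independent replicates pooled in one run (error bars
#'   are computed across replicates).
#' @param duration Simulated duration in hours (canonical 80).
#' @param dt Time step in seconds; defaults 1 (sperm) / 10 (oocyte).
#' @param seed Master RNG seed.
#' @param age_group `"20s"`, `"30s"` or `"40s"`.
#' @param with_endometriosis Logical.
#' @param record_trajectories Record sampled `(t, s, r_frac, theta)` paths.
#' @param trajectory_stride Record every k-th step.
#' @return Object of class `simulation_design`.
#' @export
simulation_design <- function(kind = c("sperm", "oocyte"),
                              n_agents = if (kind == "sperm") 10000L else 100L,
                              n_replicates = 1L, duration = 80,
                              dt = if (kind == "sperm") 1 else 10,
                              seed = 1L, age_group = "20s",
                              with_endometriosis = FALSE,
                              record_trajectories = FALSE,
                              trajectory_stride = 60L) {
  kind <- match.arg(kind)
  .match_age(age_group)
  stopifnot(n_agents >= 1, n_replicates >= 1, duration >= 0, dt > 0)
  structure(list(kind = kind, n_agents = as.integer(n_agents),
                 n_replicates = as.integer(n_replicates),
                 duration = duration, dt = dt, seed = as.integer(seed),
                 age_group = age_group,
                 with_endometriosis = with_endometriosis,
                 record_trajectories = record_trajectories,
                 trajectory_stride = as.integer(trajectory_stride)),
            class = "simulation_design")
}

#' Calibrated default parameters of the transport model
#'
#' Per-age calibration constants (wall/lesion sticking hazards, near-wall
#' friction factors) together with the physical defaults of the flow, sperm
#' and oocyte sub-models. The hazards were fitted once, by coarse bisection
#' (see `scripts/calibrate.R`), so that the six canonical configurations
#' reproduce the reference outcome statistics; they are ordinary config
#' values and can be overridden.
#'
#' @param age_group `"20s"`, `"30s"` or `"40s"`.
#' @return Nested parameter list.
#' @export
default_params <- function(age_group = "20s") {
  .match_age(age_group)
  list(
    age_group = age_group,
    c_cal = 0.003,            # ciliary slip calibration constant
    compliance = 0.2,         # wall pressure-to-displacement factor
    kappa = 13, nu = 0.49,    # wall stiffness (kPa) and Poisson ratio
    protrusion_frac = 0.4,    # lesion radial encroachment fraction
    sperm = list(
      control = beat_control(),
      near_wall = 0.8,        # r_frac above which wall interactions act
      sigma_r = 0.05,         # radial diffusion, r_frac units / sqrt(s)
      sigma_theta = 0.10,     # azimuthal diffusion, rad / sqrt(s)
      f_age = c("20s" = 1.00, "30s" = 0.85, "40s" = 0.70)[[age_group]],
      h_wall = c("20s" = 1.34e-4, "30s" = 3.70e-4,
                 "40s" = 9.78e-4)[[age_group]],     # 1/s near the wall
      h_lesion = c("20s" = 1.31e-4, "30s" = 1.56e-3,
                   "40s" = 8.86e-3)[[age_group]],   # 1/s in a lesion zone
      crowding = 0.05,        # local-density sticking multiplier gain
      goal_frac = 0.7,        # goal threshold, fraction of ampulla length
      hyperactivation = "on_ampulla_entry"),
    oocyte = list(
      model = oocyte_model(),
      r_frac0 = 0.8,          # near-wall riding position
      r_band = c(0.7, 0.9),   # radial band the settled sphere rides in
      sigma_r = 0.002, sigma_theta = 0.005,
      h_wall = c("20s" = 1.06e-7, "30s" = 2.14e-7,
                 "40s" = 3.50e-7)[[age_group]],     # 1/s everywhere
      h_lesion = c("20s" = 3.04e-6, "30s" = 4.09e-6,
                   "40s" = 4.30e-6)[[age_group]],   # 1/s in a lesion zone
      squeeze_eps0 = 0.2))
}

# Cache of RFT propulsion speeds keyed by the beat control + mode, so the
# stepper does not recompute the beat integration on every run.
.speed_cache <- new.env(parent = emptyenv())

sperm_speeds <- function(control = beat_control(),
                         mucus = mucus_properties()) {
  key <- paste(unlist(control), mucus$viscosity_intercept, collapse = "_")
  if (!is.null(.speed_cache[[key]])) return(.speed_cache[[key]])
  geom <- sperm_geometry()
  normal <- propulsion_velocity(geom, dynein_motors(hyperactivated = FALSE),
                                mucus, control)
  hyper <- propulsion_velocity(geom, dynein_motors(hyperactivated = TRUE),
                               mucus, control)
  out <- list(normal = normal, hyper = hyper)
  .speed_cache[[key]] <- out
  out
}

#' Initial agent positions
#'
#' Sperm start uniformly at random inside the intramural lumen; each oocyte
#' run starts uniformly at random within the infundibulum. Reproducible
#' from the design seed.
#'
#' @param design A `simulation_design`.
#' @param tube A `tube_model`.
#' @param params Parameter list from [default_params()].
#' @return List of state vectors (one entry per agent).
#' @export
init_positions <- function(design, tube, params = default_params(design$age_group)) {
  n <- design$n_agents * design$n_replicates
  set.seed(design$seed)
  if (design$kind == "sperm") {
    b <- region_bounds(tube, "intramural")
    s <- stats::runif(n, b[1], b[2])
    r_frac <- sqrt(stats::runif(n)) * 0.95   # uniform over the disc
  } else {
    b <- region_bounds(tube, "infundibulum")
    s <- stats::runif(n, b[1], b[2])
    r_frac <- rep(params$oocyte$r_frac0, n) +
      stats::runif(n, -0.02, 0.02)
  }
  list(kind = design$kind,
       s = s, r_frac = r_frac,
       theta = stats::runif(n, 0, 2 * pi),
       mode = integer(n),                 # 0 normal, 1 hyperactivated
       status = integer(n),               # 0 swimming, 1 stuck, 2 reached
       stuck_at = integer(n),             # 0 none, -1 wall, >0 lesion id
       t_final = rep(NA_real_, n),
       replicate = rep(seq_len(design$n_replicates),
                       each = design$n_agents))
}

# Static per-run context shared by every step: tube, flow, lesion vectors,
# thresholds and cached speeds.
.run_context <- function(design, tube, params) {
  material <- wall_material(kappa = params$kappa, L_ref = tube$total_length,
                            nu = params$nu, compliance = params$compliance)
  flow <- flow_model(tube, material = material,
                     cilia = cilia_field(density = tube$cilia_density,
                                         c_cal = params$c_cal))
  les <- tube$lesions
  amp <- region_bounds(tube, "ampulla")
  ctx <- list(
    tube = tube, flow = flow,
    L = tube$total_length,
    amp_start = amp[1],
    s_goal = amp[1] + params$sperm$goal_frac * (amp[2] - amp[1]),
    v_slip = cilia_slip_speed(flow$cilia),
    les_center = vapply(les, function(l) l$center_s, numeric(1)),
    les_azim = vapply(les, function(l) l$azimuth, numeric(1)),
    les_half_len = vapply(les, function(l) l$length / 2, numeric(1)),
    les_ang_hw = if (length(les))
      vapply(les, function(l)
        (l$width / 2) / .base_radius(tube, l$center_s), numeric(1))
      else numeric(0),
    les_radius = if (length(les))
      vapply(les, function(l)
        .base_radius(tube, l$center_s) * (1 - l$protrusion_frac), numeric(1))
      else numeric(0),
    params = params)
  if (design$kind == "sperm") {
    sp <- sperm_speeds(params$sperm$control)
    ctx$v_normal <- sp$normal$speed / 1000   # um/s -> mm/s
    ctx$v_hyper <- sp$hyper$speed / 1000
    ctx$excursion_ratio <- sp$hyper$lateral_excursion /
      max(sp$normal$lateral_excursion, 1e-9)
  }
  ctx
}

# In-zone indicator for every (s, theta) against every lesion; returns the
# id (0 = none) of the first lesion whose footprint covers the agent.
.lesion_zone <- function(ctx, s, theta) {
  zone <- integer(length(s))
  for (j in seq_along(ctx$les_center)) {
    dth <- atan2(sin(theta - ctx$les_azim[j]), cos(theta - ctx$les_azim[j]))
    hit <- zone == 0L &
      abs(s - ctx$les_center[j]) < ctx$les_half_len[j] &
      abs(dth) < ctx$les_ang_hw[j]
    zone[hit] <- j
  }
  zone
}

# Crowding multiplier on sticking: local agent density (2 mm bins along s)
# relative to a uniform occupation of the currently spanned range.
.crowding_multiplier <- function(s, gain) {
  if (gain <= 0 || length(s) < 10L) return(rep(1, length(s)))
  rng <- range(s)
  if (diff(rng) < 4) return(rep(1, length(s)))
  bins <- pmin(pmax(1L, as.integer((s - rng[1]) / 2) + 1L),
               as.integer(diff(rng) / 2) + 1L)
  cnt <- tabulate(bins)
  ubar <- length(s) / length(cnt)
  1 + gain * pmax(0, cnt[bins] / ubar - 1)
}

# Advance the full state by one time step. `active` indexes swimming agents.
.advance <- function(state, ctx, design, t, active) {
  p <- ctx$params
  dt <- design$dt
  n <- length(active)
  s <- state$s[active]; r <- state$r_frac[active]; th <- state$theta[active]

  gs <- .flow_grid_state(ctx$flow, t)
  ubar <- stats::approx(ctx$flow$s_grid, gs$ubar, s, rule = 2)$y
  u <- 2 * ubar * (1 - r^2) - ctx$v_slip * pmax(0, (r - 0.6) / 0.4)

  if (state$kind == "sperm") {
    ps <- p$sperm
    near <- r > ps$near_wall
    v_self <- ifelse(state$mode[active] == 1L, ctx$v_hyper, ctx$v_normal)
    v_self <- v_self * ifelse(near, ps$f_age, 1)
    s_new <- s + dt * (v_self + u)
    sig_r <- ps$sigma_r * ifelse(state$mode[active] == 1L,
                                 min(ctx$excursion_ratio, 3), 1)
    r_new <- r + stats::rnorm(n, 0, sig_r * sqrt(dt))
    th_new <- th + stats::rnorm(n, 0, ps$sigma_theta * sqrt(dt))
  } else {
    po <- p$oocyte
    oo <- po$model
    t_h <- t / 3600
    D <- 2 * stats::approx(ctx$flow$s_grid, gs$R, s, rule = 2)$y
    dEff <- effective_diameter(oo, t_h)
    H <- hindrance_factor(oo, dEff / D)
    s_new <- s + dt * u * H
    r_new <- r + stats::rnorm(n, 0, po$sigma_r * sqrt(dt))
    th_new <- th + stats::rnorm(n, 0, po$sigma_theta * sqrt(dt))
  }

  # reflecting boundaries
  s_new <- ifelse(s_new < 0 & state$kind == "sperm", -s_new, s_new)
  s_new <- ifelse(s_new > ctx$L, 2 * ctx$L - s_new, s_new)
  rb <- if (state$kind == "oocyte") p$oocyte$r_band else c(0, 0.98)
  r_new <- ifelse(r_new < rb[1], 2 * rb[1] - r_new, r_new)
  r_new <- ifelse(r_new > rb[2], 2 * rb[2] - r_new, r_new)
  r_new <- pmin(pmax(r_new, rb[1]), rb[2])

  zone <- if (length(ctx$les_center)) .lesion_zone(ctx, s_new, th_new)
          else integer(n)

  if (state$kind == "sperm") {
    ps <- p$sperm
    near <- r_new > ps$near_wall
    hazard <- ps$h_wall * near + ps$h_lesion * (zone > 0L & near)
    hazard <- hazard * .crowding_multiplier(s_new, ps$crowding)
  } else {
    po <- p$oocyte
    rough <- roughness_factor(po$model, t / 3600)
    hazard <- (po$h_wall + po$h_lesion * (zone > 0L)) * rough
  }
  u01 <- stats::runif(n)
  stick <- u01 < (1 - exp(-hazard * dt))

  # oocyte mechanical occlusion at a lesion-narrowed section
  if (state$kind == "oocyte" && any(zone > 0L)) {
    po <- p$oocyte
    inz <- which(zone > 0L)
    D_les <- 2 * ctx$les_radius[zone[inz]]
    blocked <- !vapply(D_les, function(d)
      oocyte_can_pass(po$model, d, t / 3600, po$squeeze_eps0), logical(1))
    stick[inz[blocked]] <- TRUE
  }

  reached <- if (state$kind == "sperm") s_new >= ctx$s_goal else s_new <= 0
  reached <- reached & !stick

  state$s[active] <- s_new
  state$r_frac[active] <- r_new
  state$theta[active] <- th_new %% (2 * pi)
  if (state$kind == "sperm" &&
      p$sperm$hyperactivation == "on_ampulla_entry") {
    enter <- s_new >= ctx$amp_start & state$mode[active] == 0L
    state$mode[active][enter] <- 1L
  } else if (state$kind == "sperm" && p$sperm$hyperactivation == "always") {
    state$mode[active] <- 1L
  }
  idx_stick <- active[stick]
  state$status[idx_stick] <- 1L
  state$stuck_at[idx_stick] <- ifelse(zone[stick] > 0L, zone[stick], -1L)
  state$t_final[idx_stick] <- (t + dt) / 3600
  idx_reach <- active[reached]
  state$status[idx_reach] <- 2L
  state$t_final[idx_reach] <- (t + dt) / 3600
  state
}

#' Run a transport simulation
#'
#' Initialises all agents for the design, steps them through the flow until
#' every agent is absorbed (stuck or reached its goal) or the simulated
#' duration elapses, and returns the per-agent outcome records. Sperm reach
#' their goal by crossing into the fertilization-site window of the
#' ampulla; oocytes by crossing `s = 0` into the uterine cavity.
#'
#' @param design A `simulation_design`.
#' @param tube A `tube_model`; built from the design's age/endometriosis
#'   flags when omitted.
#' @param params Parameter list; defaults to
#'   `default_params(design$age_group)`.
#' @return Object of class `transport_result` with elements `design`,
#'   `agents` (data frame: id, replicate, status, mode, stuck_at, t_final,
#'   final_s) and optional `trajectories`.
#' @export
run_transport <- function(design, tube = NULL,
                          params = default_params(design$age_group)) {
  if (is.null(tube))
    tube <- build_tube(design$age_group, design$with_endometriosis,
                       overrides = list(
                         lesion_protrusion_frac = params$protrusion_frac))
  ctx <- .run_context(design, tube, params)
  state <- init_positions(design, tube, params)

  n_steps <- ceiling(design$duration * 3600 / design$dt)
  traj <- if (design$record_trajectories) list() else NULL
  t <- 0
  for (k in seq_len(n_steps)) {
    active <- which(state$status == 0L)
    if (!length(active)) break
    state <- .advance(state, ctx, design, t, active)
    t <- t + design$dt
    if (!is.null(traj) && (k %% design$trajectory_stride == 0L)) {
      traj[[length(traj) + 1L]] <- data.frame(
        t = t / 3600, id = seq_along(state$s), s = state$s,
        r_frac = state$r_frac, theta = state$theta, status = state$status)
    }
  }

  agents <- data.frame(
    id = seq_along(state$s),
    replicate = state$replicate,
    kind = state$kind,
    status = c("swimming", "stuck", "reached_goal")[state$status + 1L],
    mode = ifelse(state$kind == "sperm",
                  c("normal", "hyperactivated")[state$mode + 1L], "n/a"),
    stuck_at = ifelse(state$stuck_at > 0L,
                      paste0("lesion_", state$stuck_at),
                      ifelse(state$stuck_at < 0L, "wall", "none")),
    t_final = state$t_final,
    final_s = state$s,
    stringsAsFactors = FALSE)

  structure(list(design = design, tube = tube, params = params,
                 agents = agents,
                 trajectories = if (!is.null(traj)) do.call(rbind, traj)),
            class = "transport_result")
}

#' Advance a single sperm agent by one step
#'
#' Single-agent wrapper around the vectorised stepper, mainly useful for
#' inspecting the update rule.
#'
#' @param agent List with `s`, `r_frac`, `theta`, `mode` ("normal" or
#'   "hyperactivated"), `status` ("swimming", ...).
#' @param tube,params,design Context objects; the design supplies `dt`.
#' @param t Current time (s).
#' @return Updated agent list with `status`, `stuck_at`, `t_final` fields.
#' @export
step_sperm <- function(agent, tube, params = default_params(tube$age_group),
                       design = simulation_design("sperm", n_agents = 1L,
                                                  age_group = tube$age_group),
                       t = 0) {
  .step_single(agent, "sperm", tube, params, design, t)
}

#' Advance a single oocyte agent by one step
#'
#' @inheritParams step_sperm
#' @export
step_oocyte <- function(agent, tube, params = default_params(tube$age_group),
                        design = simulation_design("oocyte", n_agents = 1L,
                                                   age_group = tube$age_group),
                        t = 0) {
  .step_single(agent, "oocyte", tube, params, design, t)
}

.step_single <- function(agent, kind, tube, params, design, t) {
  stopifnot(identical(agent$status %||% "swimming", "swimming"))
  ctx <- .run_context(design, tube, params)
  state <- list(kind = kind, s = agent$s, r_frac = agent$r_frac,
                theta = agent$theta %||% 0,
                mode = as.integer(identical(agent$mode, "hyperactivated")),
                status = 0L, stuck_at = 0L, t_final = NA_real_,
                replicate = 1L)
  state <- .advance(state, ctx, design, t, 1L)
  list(s = state$s, r_frac = state$r_frac, theta = state$theta,
       mode = c("normal", "hyperactivated")[state$mode + 1L],
       status = c("swimming", "stuck", "reached_goal")[state$status + 1L],
       stuck_at = state$stuck_at, t_final = state$t_final)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.transport_result <- function(x, ...) {
  tab <- table(x$agents$status)
  cat("Transport simulation (", x$design$kind, ", ", x$design$age_group,
      ", ", if (x$design$with_endometriosis) "endometriosis" else "normal",
      ")\n", sep = "")
  cat("  agents:", nrow(x$agents),
      "  replicates:", x$design$n_replicates, "\n")
  for (nm in names(tab)) cat(sprintf("  %-13s %d\n", nm, tab[[nm]]))
  invisible(x)
}
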