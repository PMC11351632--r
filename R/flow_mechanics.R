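# Peristalsis-ciliary mucus flow inside a tube model, via a reduced-order
# lubrication/kinematic approximation:
#   * the muscular wall is a neo-Hookean material; the printed constitutive
#     law (strain energy + Lame-parameter formulas) is implemented exactly,
#     and a linear compliance derived from the shear Lame parameter maps the
#     travelling peristaltic pressure wave to a radial wall displacement;
#   * the axial peristaltic velocity follows from mass conservation through
#     the time-varying radius, with a Poiseuille (1 - r^2) profile;
#   * cilia enter as a near-wall slip velocity directed pro-uterus, decaying
#     linearly to zero at 60% of the radius.
# Internal units: mm, s, kPa. 1 mmHg = 0.1333 kPa.

.MMHG_TO_KPA <- 0.133322

#' Lame parameters of the tubal wall from stiffness and geometry
#'
#' Converts the wall stiffness `kappa` (kPa), a reference length `L_ref`
#' (mm), a reference luminal area `A_ref` (mm^2) and the Poisson ratio `nu`
#' into the two Lame parameters of the neo-Hookean wall model:
#' \deqn{\lambda = \frac{\nu L \kappa}{(1+\nu)(1-2\nu) A}, \qquad
#'       \mu = \frac{L \kappa}{2 A (1+\nu)}.}
#'
#' @param kappa Wall stiffness in kPa (physiological range 12-14).
#' @param L_ref Reference length in mm (85-105).
#' @param A_ref Reference luminal area in mm^2 (5-40).
#' @param nu Poisson ratio, in (0, 0.5); 0.49 for the muscle layer.
#' @return Named vector `c(mu_lame = , lambda_lame = )` in kPa.
#' @export
lame_parameters <- function(kappa, L_ref, A_ref, nu) {
  if (any(c(kappa, L_ref, A_ref) <= 0)) stop("kappa, L_ref, A_ref must be > 0")
  if (nu <= 0 || nu >= 0.5)
    stop("nu must lie strictly in (0, 0.5); nu = 0.5 is the incompressible limit")
  mu <- L_ref * kappa / (2 * A_ref * (1 + nu))
  lambda <- nu * L_ref * kappa / ((1 + nu) * (1 - 2 * nu) * A_ref)
  c(mu_lame = mu, lambda_lame = lambda)
}

#' Wall material of the tube
#'
#' @param kappa Stiffness (kPa), 12-14.
#' @param L_ref,A_ref Reference length (mm) and area (mm^2) entering the
#'   Lame-parameter formulas.
#' @param nu Poisson ratio.
#' @param compliance Dimensionless factor of the linear pressure-to-
#'   displacement map used by [wall_displacement()].
#' @return Object of class `wall_material`.
#' @export
wall_material <- function(kappa = 13, L_ref = 95, A_ref = 20, nu = 0.49,
                          compliance = 1) {
  if (kappa < 12 || kappa > 14)
    stop("wall stiffness kappa must lie in 12-14 kPa")
  lp <- lame_parameters(kappa, L_ref, A_ref, nu)
  structure(list(kappa = kappa, L_ref = L_ref, A_ref = A_ref, nu = nu,
                 mu_lame = unname(lp["mu_lame"]),
                 lambda_lame = unname(lp["lambda_lame"]),
                 compliance = compliance),
            class = "wall_material")
}

#' Neo-Hookean strain energy density of the wall
#'
#' Compressible neo-Hookean energy, as adopted for the mucosal/muscular
#' layer:
#' \deqn{W = \frac{\mu}{2}(I_1 - 3) + \mu \ln J + \frac{\lambda}{2}(\ln J)^2.}
#' Note the sign of the middle term: the common compressible form carries
#' \eqn{-\mu \ln J}; here the law is implemented with \eqn{+\mu \ln J}, the
#' form this model adopts (see the methods vignette).
#'
#' @param material A `wall_material` (or any list with `mu_lame`,
#'   `lambda_lame`).
#' @param I1 First invariant of the right Cauchy-Green tensor (vectorised).
#' @param J Determinant of the deformation gradient, > 0 (vectorised).
#' @return Energy density in kPa.
#' @export
strain_energy <- function(material, I1, J) {
  if (any(J <= 0)) stop("J must be positive")
  mu <- material$mu_lame; lambda <- material$lambda_lame
  mu / 2 * (I1 - 3) + mu * log(J) + lambda / 2 * log(J)^2
}

#' Travelling peristaltic contraction wave
#'
#' @param amplitude_p Contraction intensity in mmHg (default 20).
#' @param frequency Contractions per minute (default 1.5, i.e. 40 s period).
#' @param direction `"pro_ovary"` (travels toward increasing s) or
#'   `"pro_uterus"`.
#' @param wavelength Wavelength in mm; `NA` means "half the ampulla length"
#'   and is resolved against the tube when the flow model is assembled.
#' @param origin_s Arclength where the wave is initiated (mm).
#' @param phase Phase offset in radians.
#' @return Object of class `peristalsis_wave`.
#' @export
peristalsis_wave <- function(amplitude_p = 20, frequency = 1.5,
                             direction = c("pro_ovary", "pro_uterus"),
                             wavelength = NA_real_, origin_s = 0, phase = 0) {
  direction <- match.arg(direction)
  structure(list(amplitude_p = amplitude_p, frequency = frequency,
                 direction = direction, wavelength = wavelength,
                 origin_s = origin_s, phase = phase),
            class = "peristalsis_wave")
}

#' Ciliary field on the mucosal layer
#'
#' @param density Ciliated-cell density per mm^2 (age dependent:
#'   2000/1600/1400 for the 20s/30s/40s groups).
#' @param beat_frequency Cilia beat frequency in Hz (default 5.4).
#' @param cilium_length Cilium length in micrometres (default 7).
#' @param c_cal Dimensionless calibration constant folding the stroke
#'   efficiency into the slip-velocity law
#'   `v = c_cal * density * beat_frequency * length^2`.
#' @return Object of class `cilia_field`.
#' @export
cilia_field <- function(density, beat_frequency = 5.4, cilium_length = 7,
                        c_cal = 0.003) {
  structure(list(density = density, beat_frequency = beat_frequency,
                 cilium_length = cilium_length, c_cal = c_cal),
            class = "cilia_field")
}

#' Ciliary slip speed at the wall
#'
#' Magnitude of the pro-uterus near-wall slip velocity,
#' `c_cal * density * f * l^2` with the cilium length converted to mm.
#'
#' @param cilia A `cilia_field`.
#' @return Speed in mm/s.
#' @export
cilia_slip_speed <- function(cilia) {
  l_mm <- cilia$cilium_length / 1000
  cilia$c_cal * cilia$density * cilia$beat_frequency * l_mm^2
}

#' Thermophysical properties of the cervical mucus
#'
#' Defaults: density 1007 kg/m^3, specific heat 4140 J/(kg K), thermal
#' conductivity 0.627 W/(m K), and the affine shear-thinning dynamic
#' viscosity `0.02 * gamma + 0.98` Pa s. The thermal fields are stored for
#' completeness but unused: the transport model is isothermal.
#'
#' @param density kg/m^3.
#' @param specific_heat J/(kg K).
#' @param thermal_conductivity W/(m K).
#' @param viscosity_slope Pa s per unit shear rate.
#' @param viscosity_intercept Pa s at zero shear rate.
#' @return Object of class `mucus_properties`.
#' @export
mucus_properties <- function(density = 1007, specific_heat = 4140,
                             thermal_conductivity = 0.627,
                             viscosity_slope = 0.02,
                             viscosity_intercept = 0.98) {
  structure(list(density = density, specific_heat = specific_heat,
                 thermal_conductivity = thermal_conductivity,
                 viscosity_slope = viscosity_slope,
                 viscosity_intercept = viscosity_intercept),
            class = "mucus_properties")
}

#' Dynamic viscosity of the mucus at a given shear rate
#'
#' @param mucus A `mucus_properties`.
#' @param shear_rate Shear rate in 1/s, >= 0 (vectorised).
#' @return Viscosity in Pa s.
#' @export
mucus_viscosity <- function(mucus, shear_rate) {
  if (any(shear_rate < 0)) stop("shear rate must be non-negative")
  mucus$viscosity_intercept + mucus$viscosity_slope * shear_rate
}

# Resolve a wave's wavelength default (half the ampulla length).
.resolve_wavelength <- function(wave, tube) {
  if (is.na(wave$wavelength)) {
    a <- region_bounds(tube, "ampulla")
    wave$wavelength <- (a[2] - a[1]) / 2
  }
  wave
}

# Radial displacement of one wave at (s, t); d and dd/dt, unclamped.
# d(s,t) = d0(s)/2 * (1 + cos(phi)),  phi = 2*pi*((s - o)/lambda -+ t/T).
.wave_displacement <- function(wave, material, R0, s, t) {
  p_kpa <- wave$amplitude_p * .MMHG_TO_KPA
  d0 <- material$compliance * p_kpa * R0 / material$mu_lame
  T_per <- 60 / wave$frequency
  dir <- if (wave$direction == "pro_ovary") 1 else -1
  phi <- 2 * pi * ((s - wave$origin_s) / wave$wavelength - dir * t / T_per) +
    wave$phase
  list(d = d0 / 2 * (1 + cos(phi)),
       ddt = d0 / 2 * (2 * pi * dir / T_per) * sin(phi))
}

#' Radial wall displacement under the peristaltic waves
#'
#' Inward radial displacement at `(s, t)` under the superposed travelling
#' pressure waves, with amplitude `compliance * p / mu_lame * R0(s)` per
#' wave (pressure converted from mmHg to kPa), clamped so the total never
#' exceeds 90% of the resting radius.
#'
#' @param tube A `tube_model`.
#' @param material A `wall_material`.
#' @param waves A single `peristalsis_wave` or a list of them.
#' @param s Arclength in mm (vectorised).
#' @param t Time in s.
#' @return Inward displacement in mm.
#' @export
wall_displacement <- function(tube, material, waves, s, t) {
  if (inherits(waves, "peristalsis_wave")) waves <- list(waves)
  R0 <- .base_radius(tube, s)
  d <- numeric(length(s))
  for (w in waves) {
    w <- .resolve_wavelength(w, tube)
    d <- d + .wave_displacement(w, material, R0, s, t)$d
  }
  pmin(d, 0.9 * R0)
}

#' Assemble a flow model for a tube
#'
#' Bundles the wall material, peristaltic waves, ciliary field and mucus
#' rheology, and precomputes the axial grid used by the mass-conservation
#' solve in [flow_velocity()].
#'
#' @param tube A `tube_model`.
#' @param material A `wall_material`.
#' @param waves List of `peristalsis_wave` objects (default: one pro-ovary
#'   wave from the intramural end and one pro-uterus wave from the
#'   infundibulum, both at the printed 20 mmHg / 1.5 per min).
#' @param cilia A `cilia_field`; default density taken from the tube's age.
#' @param mucus A `mucus_properties`.
#' @param n_grid Axial grid size for the conservation integral.
#' @return Object of class `flow_model`.
#' @export
flow_model <- function(tube, material = wall_material(L_ref = tube$total_length),
                       waves = list(
                         peristalsis_wave(direction = "pro_ovary", origin_s = 0),
                         peristalsis_wave(direction = "pro_uterus",
                                          origin_s = tube$total_length)),
                       cilia = cilia_field(density = tube$cilia_density),
                       mucus = mucus_properties(),
                       n_grid = 257L) {
  if (inherits(waves, "peristalsis_wave")) waves <- list(waves)
  waves <- lapply(waves, .resolve_wavelength, tube = tube)
  s_grid <- seq(0, tube$total_length, length.out = n_grid)
  structure(list(tube = tube, material = material, waves = waves,
                 cilia = cilia, mucus = mucus,
                 s_grid = s_grid, R0_grid = .base_radius(tube, s_grid)),
            class = "flow_model")
}

# Grid solve of the conservation integral at time t:
# Q(s, t) = -int_0^s dA/dt ds'   with Q(0, t) = 0 at the closed uterine end.
# Returns the grid radius R, area A, flux Q and mean velocity ubar.
.flow_grid_state <- function(flow, t) {
  R0 <- flow$R0_grid
  d <- numeric(length(R0)); ddt <- numeric(length(R0))
  for (w in flow$waves) {
    wd <- .wave_displacement(w, flow$material, R0, flow$s_grid, t)
    d <- d + wd$d; ddt <- ddt + wd$ddt
  }
  clamped <- d > 0.9 * R0
  d[clamped] <- 0.9 * R0[clamped]
  ddt[clamped] <- 0
  R <- R0 - d
  A <- pi * R^2
  dAdt <- 2 * pi * R * (-ddt)
  h <- diff(flow$s_grid[1:2])
  Q <- -cumsum(c(0, (dAdt[-1] + dAdt[-length(dAdt)]) / 2 * h))
  list(R = R, A = A, Q = Q, ubar = Q / A)
}

#' Axial mucus velocity at a point
#'
#' Sum of the peristaltic component (mean velocity from mass conservation
#' through the time-varying radius, with a Poiseuille `2 * (1 - r_frac^2)`
#' profile) and the ciliary near-wall slip (pro-uterus, i.e. negative `s`
#' direction, decaying linearly from the wall to zero at `r_frac = 0.6`).
#' Positive values point pro-ovary (increasing `s`).
#'
#' @param flow A `flow_model`.
#' @param s Arclength mm (vectorised).
#' @param r_frac Fractional radial position in `[0, 1]` (0 = axis,
#'   1 = wall), recycled against `s`.
#' @param t Time in s (scalar).
#' @return Axial velocity in mm/s.
#' @export
flow_velocity <- function(flow, s, r_frac, t) {
  if (any(r_frac < 0 | r_frac > 1)) stop("r_frac must lie in [0, 1]")
  n <- max(length(s), length(r_frac))
  s <- rep_len(s, n); r_frac <- rep_len(r_frac, n)
  st <- .flow_grid_state(flow, t)
  ubar <- stats::approx(flow$s_grid, st$ubar, s, rule = 2)$y
  u_per <- 2 * ubar * (1 - r_frac^2)
  v_slip <- cilia_slip_speed(flow$cilia)
  u_cil <- -v_slip * pmax(0, (r_frac - 0.6) / 0.4)
  u_per + u_cil
}

#' Instantaneous volume flux through a cross-section
#'
#' @param flow A `flow_model`.
#' @param s Arclength mm (vectorised).
#' @param t Time s.
#' @return Peristaltic volume flux in mm^3/s (pro-ovary positive).
#' @export
flow_flux <- function(flow, s, t) {
  st <- .flow_grid_state(flow, t)
  stats::approx(flow$s_grid, st$Q, s, rule = 2)$y
}

#' Wall shear rate of the peristaltic component
#'
#' Poiseuille wall shear rate `4 * |ubar| / R` of the conservation-derived
#' mean flow; feeds the shear-thinning viscosity when drag laws are
#' evaluated near the wall.
#'
#' @param flow A `flow_model`.
#' @param s Arclength mm (vectorised).
#' @param t Time s.
#' @return Shear rate in 1/s.
#' @export
wall_shear_rate <- function(flow, s, t) {
  st <- .flow_grid_state(flow, t)
  ub <- stats::approx(flow$s_grid, st$ubar, s, rule = 2)$y
  R <- stats::approx(flow$s_grid, st$R, s, rule = 2)$y
  4 * abs(ub) / R
}
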