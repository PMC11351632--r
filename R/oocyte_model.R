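# Oocyte as a passive confined sphere advected by the peristalsis-ciliary
# flow. The corona radiata (outer cumulus layer) enlarges the effective
# diameter and roughens the surface until it sheds ~12 h after ovulation.

#' Oocyte model
#'
#' @param zona_diameter Diameter of the zona pellucida sphere (mm).
#' @param corona_diameter Diameter including the corona radiata (mm).
#' @param corona_shed_time Time after ovulation at which the corona sheds (h).
#' @param elasticity Oocyte elasticity (kPa), 10 +/- 5; softer oocytes
#'   squeeze through lesion-narrowed sections more easily.
#' @param roughness Sticking-probability multiplier while the corona is
#'   attached (>= 1; 1 after shedding).
#' @param hindrance_exponent Exponent of the confined-sphere mobility
#'   `H = (1 - (d/D)^2)^p`.
#' @return Object of class `oocyte_model`.
#' @export
oocyte_model <- function(zona_diameter = 0.12, corona_diameter = 0.4,
                         corona_shed_time = 12, elasticity = 10,
                         roughness = 2, hindrance_exponent = 1.5) {
  stopifnot(zona_diameter > 0, corona_diameter >= zona_diameter,
            corona_shed_time >= 0, roughness >= 1)
  structure(list(zona_diameter = zona_diameter,
                 corona_diameter = corona_diameter,
                 corona_shed_time = corona_shed_time,
                 elasticity = elasticity, roughness = roughness,
                 hindrance_exponent = hindrance_exponent,
                 fertilized = FALSE),
            class = "oocyte_model")
}

#' Effective oocyte diameter at time t
#'
#' Equals the corona diameter before the shedding time and the zona
#' diameter afterwards (non-increasing, single step).
#'
#' @param oocyte An `oocyte_model`.
#' @param t Time since ovulation (h), vectorised.
#' @return Diameter in mm.
#' @export
effective_diameter <- function(oocyte, t) {
  ifelse(t < oocyte$corona_shed_time,
         oocyte$corona_diameter, oocyte$zona_diameter)
}

#' Surface roughness factor of the oocyte
#'
#' Multiplier on the sticking probability: the corona radiata cells impart
#' an outer roughness, so the factor exceeds 1 before the corona sheds and
#' is exactly 1 afterwards.
#'
#' @param oocyte An `oocyte_model`.
#' @param t Time since ovulation (h), vectorised.
#' @return Dimensionless factor >= 1.
#' @export
roughness_factor <- function(oocyte, t) {
  if (any(t < 0)) stop("t must be non-negative")
  ifelse(t < oocyte$corona_shed_time, oocyte$roughness, 1)
}

# Wall-hindrance mobility H(d/D) in (0, 1]; H -> 1 as d/D -> 0 and
# decreases toward 0 as the sphere fills the lumen.
hindrance_factor <- function(oocyte, ratio) {
  ratio <- pmin(pmax(ratio, 0), 1)
  (1 - ratio^2)^oocyte$hindrance_exponent
}

#' Advection velocity of the oocyte in a local flow
#'
#' Stokes advection of a confined sphere: the oocyte translates at the
#' local flow velocity reduced by the hindrance factor
#' `H = (1 - (d/D)^2)^p`, where `d` is the effective diameter at time `t`
#' and `D` the local luminal diameter. An oocyte larger than the lumen is
#' mechanically occluded.
#'
#' @param oocyte An `oocyte_model`.
#' @param local_flow Local axial flow velocity (mm/s), vectorised.
#' @param tube_diameter Local luminal diameter (mm), recycled.
#' @param t Time since ovulation (h).
#' @param mucus A `mucus_properties` (the quasi-static Stokes limit makes
#'   the advection speed independent of the viscosity magnitude; accepted
#'   for interface completeness).
#' @return Velocity in mm/s (same sign as `local_flow`).
#' @export
drag_velocity <- function(oocyte, local_flow, tube_diameter, t,
                          mucus = mucus_properties()) {
  d <- effective_diameter(oocyte, t)
  if (any(d >= tube_diameter))
    stop("oocyte larger than the lumen: mechanical occlusion")
  local_flow * hindrance_factor(oocyte, d / tube_diameter)
}

# Squeeze-through rule at a lesion-narrowed section: the oocyte passes when
# d <= D * (1 + eps(E)) with the deformability margin eps decreasing in the
# elasticity E (kPa); eps = eps0 * (E_ref / E), E_ref = 10 kPa.
oocyte_can_pass <- function(oocyte, tube_diameter, t, eps0 = 0.2) {
  d <- effective_diameter(oocyte, t)
  eps <- eps0 * (10 / max(oocyte$elasticity, 1e-6))
  d <= tube_diameter * (1 + eps)
}
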