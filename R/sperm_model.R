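# Sperm flagellar beat and propulsion.
#
# The beat is generated from discrete dynein sliding forces: each of the
# n_motors sites along the flagellum contributes a local curvature
# proportional to its sliding force, travelling as a wave in the beat phase;
# the 3D flagellar shape follows by integrating the Frenet-Serret system
# (with a small constant torsion) along the arclength. Propulsion converts
# the beat kinematics into a swimming velocity with Gray-Hancock resistive
# force theory: slender-body tangential/normal drag on each flagellar
# segment plus bluff-body drag on the head/midpiece, solved for the
# force-free and torque-free rigid-body motion at each phase and averaged
# over a beat. Lengths in micrometres, forces in micronewtons.

#' Sperm geometry
#'
#' Default morphology of a normal human sperm cell: elliptical head
#' 4.2 x 2.85 um tapering to a 0.46 um tip, midpiece 4 um long and 1 um in
#' diameter, and a 55 um flagellum whose diameter tapers from 1 um at the
#' base to 0.1 um at the distal end.
#'
#' @param head_length,head_width,head_tip Head dimensions (um).
#' @param midpiece_length,midpiece_diameter Midpiece dimensions (um).
#' @param flagellum_length Flagellum length (um).
#' @param flagellum_diameter_base,flagellum_diameter_tip Flagellum taper (um).
#' @return Object of class `sperm_geometry`.
#' @export
sperm_geometry <- function(head_length = 4.2, head_width = 2.85,
                           head_tip = 0.46, midpiece_length = 4,
                           midpiece_diameter = 1, flagellum_length = 55,
                           flagellum_diameter_base = 1,
                           flagellum_diameter_tip = 0.1) {
  structure(list(head_length = head_length, head_width = head_width,
                 head_tip = head_tip, midpiece_length = midpiece_length,
                 midpiece_diameter = midpiece_diameter,
                 flagellum_length = flagellum_length,
                 flagellum_diameter_base = flagellum_diameter_base,
                 flagellum_diameter_tip = flagellum_diameter_tip),
            class = "sperm_geometry")
}

#' Dynein motor array along the flagellum
#'
#' One hundred motor sites at equal arclength intervals by default. The
#' sliding force per motor is 2e-6 uN in the normal (progressive) mode and
#' 5e-6 uN in the hyperactivated mode; hyperactivation also switches on an
#' asymmetry offset in the curvature wave, producing the large, asymmetric
#' beat characteristic of that mode.
#'
#' @param n_motors Number of motor sites (>= 10).
#' @param hyperactivated Logical mode switch.
#' @param sliding_force Force per motor in uN; defaults by mode.
#' @return Object of class `dynein_motors` with fields `n_motors`,
#'   `sliding_force`, `hyperactivated` and `positions` (arclength
#'   fractions).
#' @export
dynein_motors <- function(n_motors = 100L, hyperactivated = FALSE,
                          sliding_force = NULL) {
  if (n_motors < 10L) stop("n_motors must be at least 10")
  if (is.null(sliding_force))
    sliding_force <- if (hyperactivated) 5e-6 else 2e-6
  structure(list(n_motors = as.integer(n_motors),
                 sliding_force = sliding_force,
                 hyperactivated = hyperactivated,
                 positions = (seq_len(n_motors) - 0.5) / n_motors),
            class = "dynein_motors")
}

#' Beat-generation control constants
#'
#' The force-to-curvature gain `k_F`, the number of curvature wavelengths on
#' the flagellum, the constant torsion making the beat weakly
#' three-dimensional, the beat frequency, and the hyperactivated asymmetry
#' offset are calibration constants of the reduced-order beat model (the
#' printed quantities are the motor count and the two sliding forces).
#'
#' @param k_F Curvature per unit sliding force (1/(um * uN)).
#' @param n_waves Curvature wavelengths along the flagellum.
#' @param torsion Constant torsion (1/um).
#' @param beat_frequency Beat frequency (Hz).
#' @param kappa_asym Hyperactivated curvature offset (1/um); applied only
#'   when the motor array is hyperactivated.
#' @return List of class `beat_control`.
#' @export
beat_control <- function(k_F = 5e4, n_waves = 1.5, torsion = 0.01,
                         beat_frequency = 10, kappa_asym = 0.035) {
  structure(list(k_F = k_F, n_waves = n_waves, torsion = torsion,
                 beat_frequency = beat_frequency, kappa_asym = kappa_asym),
            class = "beat_control")
}

#' Flagellar shape at one beat phase
#'
#' Curvature at motor site i:
#' `kappa_i = k_F * F * sin(2*pi*(xi_i - phase/(2*pi)) * n_waves) + kappa_asym`,
#' with `kappa_asym > 0` only in the hyperactivated mode. The 3D shape is
#' obtained by integrating the Frenet-Serret equations along the flagellum
#' with this curvature and the constant torsion, using an exact per-step
#' rotation of the (T, N, B) frame about the Darboux vector, which keeps the
#' frame orthonormal to machine precision and the arclength conserved.
#'
#' @param geometry A `sperm_geometry`.
#' @param motors A `dynein_motors`.
#' @param phase Beat phase in radians.
#' @param control A `beat_control`.
#' @param n_sub Integration substeps per motor interval.
#' @return List of class `beat_pattern`: `xi` (fractions), `curvature`
#'   (1/um), `shape` (n_motors x 3 matrix, um, base at origin, base tangent
#'   +x), `frame` (final 3x3 frame), `arclength` (polyline chord sum, um).
#' @export
beat_pattern <- function(geometry, motors, phase = 0,
                         control = beat_control(), n_sub = 4L) {
  Lf <- geometry$flagellum_length
  if (Lf <= 0) stop("zero-length flagellum")
  xi <- motors$positions
  kasym <- if (motors$hyperactivated) control$kappa_asym else 0
  curv_at <- function(x)
    control$k_F * motors$sliding_force *
      sin(2 * pi * (x - phase / (2 * pi)) * control$n_waves) + kasym

  n <- motors$n_motors
  h <- Lf / n / n_sub
  Tv <- c(1, 0, 0); Nv <- c(0, 1, 0); Bv <- c(0, 0, 1)
  p <- c(0, 0, 0)
  shape <- matrix(0, n, 3L)
  tau <- control$torsion
  x <- 0
  for (i in seq_len(n)) {
    for (k in seq_len(n_sub)) {
      kap <- curv_at((x + h / 2) / Lf)
      # Darboux rotation: omega = tau*T + kappa*B, frame rotates by |omega|*h
      om <- tau * Tv + kap * Bv
      ang <- sqrt(sum(om^2)) * h
      if (ang > 0) {
        ax <- om / sqrt(sum(om^2))
        rot <- function(v) {
          v * cos(ang) + .cross3(ax, v) * sin(ang) +
            ax * sum(ax * v) * (1 - cos(ang))
        }
        p <- p + Tv * h  # advance along current tangent
        Tv <- rot(Tv); Nv <- rot(Nv); Bv <- rot(Bv)
      } else {
        p <- p + Tv * h
      }
      x <- x + h
    }
    shape[i, ] <- p
  }
  arc <- sum(sqrt(rowSums((shape[-1, , drop = FALSE] -
                           shape[-n, , drop = FALSE])^2))) +
    sqrt(sum(shape[1, ]^2))
  structure(list(xi = xi, curvature = curv_at(xi), shape = shape,
                 frame = rbind(Tv, Nv, Bv), arclength = arc,
                 phase = phase, control = control, motors = motors,
                 geometry = geometry),
            class = "beat_pattern")
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Gray-Hancock drag coefficients per unit length (uN s / um^2) for a slender
# filament of radius a in fluid of viscosity mu (Pa s).
rft_drag_coefficients <- function(mu_pa_s, filament_length, filament_radius) {
  mu <- mu_pa_s * 1e-6  # Pa s -> uN s / um^2
  lr <- log(2 * filament_length / filament_radius)
  c(C_t = 2 * pi * mu / (lr - 0.5),
    C_n = 4 * pi * mu / (lr + 0.5))
}

#' Propulsion velocity from the flagellar beat (resistive force theory)
#'
#' Samples the beat over one cycle, computes the shape-change velocity of
#' every flagellar segment, and solves the force-free and torque-free
#' rigid-body problem (6x6 grand resistance matrix from Gray-Hancock drag on
#' the flagellum plus prolate-spheroid drag on the head and midpiece, which
#' contribute drag only). The per-phase rigid motion is composed over the
#' cycle to give the swimming path.
#'
#' @param geometry A `sperm_geometry`.
#' @param motors A `dynein_motors`.
#' @param mucus A `mucus_properties`; the viscosity at zero shear enters the
#'   drag coefficients (the swimming speed of a force-free swimmer depends
#'   only on drag ratios, so speed is insensitive to the absolute value).
#' @param control A `beat_control`.
#' @param n_phases Phase samples per beat cycle.
#' @param include_head Include head/midpiece drag (disable to compare with
#'   the classical head-free small-amplitude formula).
#' @param window Time window (s) over which the straight-line mean-path
#'   speed is measured; the asymmetric hyperactivated beat yaws the swimmer,
#'   so its straight-line progress over this window falls below the
#'   symmetric mode's even though the instantaneous thrust is larger.
#' @return List: `speed` (straight-line mean-path speed, um/s),
#'   `forward_speed` (mean speed along the body axis, um/s),
#'   `lateral_excursion` (rms lateral amplitude of the beat envelope, um),
#'   `yaw_rate` (rad/s).
#' @export
propulsion_velocity <- function(geometry, motors, mucus = mucus_properties(),
                                control = beat_control(), n_phases = 24L,
                                include_head = TRUE, window = 1) {
  # one shape cycle of the curvature wave spans phase 2*pi / n_waves
  phases <- seq(0, 2 * pi, length.out = n_phases + 1L)[-(n_phases + 1L)]
  shapes <- lapply(phases, function(ph)
    beat_pattern(geometry, motors, ph, control)$shape)
  f_cycle <- control$beat_frequency  # cycles of phase 2*pi per second
  dt <- (1 / f_cycle) / n_phases

  a_mean <- (geometry$flagellum_diameter_base +
             geometry$flagellum_diameter_tip) / 4
  cf <- rft_drag_coefficients(mucus$viscosity_intercept,
                              geometry$flagellum_length, a_mean)
  C_t <- cf["C_t"]; C_n <- cf["C_n"]
  n <- motors$n_motors
  hseg <- geometry$flagellum_length / n
  mu <- mucus$viscosity_intercept * 1e-6

  # head + midpiece translational drag (prolate spheroid approximated by an
  # equivalent sphere of the same volume) acting at the flagellum base
  head_D <- if (include_head) {
    vol <- 4 / 3 * pi * (geometry$head_length / 2) *
      (geometry$head_width / 2)^2 +
      pi * (geometry$midpiece_diameter / 2)^2 * geometry$midpiece_length
    a_eq <- (3 * vol / (4 * pi))^(1 / 3)
    6 * pi * mu * a_eq
  } else 0

  U <- matrix(0, n_phases, 3L)
  Om <- matrix(0, n_phases, 3L)
  for (k in seq_len(n_phases)) {
    X <- shapes[[k]]
    Xp <- shapes[[if (k == n_phases) 1L else k + 1L]]
    Xm <- shapes[[if (k == 1L) n_phases else k - 1L]]
    V <- (Xp - Xm) / (2 * dt)              # shape-change velocity, um/s
    Tseg <- rbind(X[1, ] / sqrt(sum(X[1, ]^2)),
                  (X[-1, ] - X[-n, ]) /
                    sqrt(rowSums((X[-1, ] - X[-n, ])^2)))
    A <- matrix(0, 3, 3); Bm <- matrix(0, 3, 3)
    Cm <- matrix(0, 3, 3); Dm <- matrix(0, 3, 3)
    Fv <- numeric(3); Tq <- numeric(3)
    for (i in seq_len(n)) {
      tt <- Tseg[i, ]
      Di <- (C_t * tcrossprod(tt) + C_n * (diag(3) - tcrossprod(tt))) * hseg
      Si <- matrix(c(0, X[i, 3], -X[i, 2],
                     -X[i, 3], 0, X[i, 1],
                     X[i, 2], -X[i, 1], 0), 3, 3)  # [r]x, column form
      A <- A + Di
      Bm <- Bm - Di %*% Si
      Cm <- Cm + Si %*% Di
      Dm <- Dm - Si %*% Di %*% Si
      Fv <- Fv - Di %*% V[i, ]
      Tq <- Tq - Si %*% Di %*% V[i, ]
    }
    if (include_head) {
      A <- A + head_D * diag(3)
      Dm <- Dm + 8 * pi * mu * ((geometry$head_length / 2))^3 * diag(3)
    }
    M <- rbind(cbind(A, Bm), cbind(Cm, Dm))
    sol <- solve(M, c(Fv, Tq))
    U[k, ] <- sol[1:3]; Om[k, ] <- sol[4:6]
  }

  # compose the rigid motion over the measurement window
  n_steps <- max(1L, round(window / dt))
  Rb <- diag(3); p <- c(0, 0, 0)
  fwd <- numeric(n_steps)
  for (j in seq_len(n_steps)) {
    k <- ((j - 1L) %% n_phases) + 1L
    p <- p + Rb %*% U[k, ] * dt
    fwd[j] <- U[k, 1]
    w <- Om[k, ]; ang <- sqrt(sum(w^2)) * dt
    if (ang > 1e-14) {
      ax <- w / sqrt(sum(w^2))
      K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0),
                  3, 3)
      Rb <- Rb %*% (diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K)
    }
  }
  lat <- mean(vapply(shapes, function(X) stats::sd(X[, 2]), numeric(1)))
  list(speed = sqrt(sum(p^2)) / (n_steps * dt),
       forward_speed = -mean(fwd),
       lateral_excursion = lat,
       yaw_rate = mean(sqrt(rowSums(Om^2))))
}
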