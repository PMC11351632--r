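# Age-group lookup tables ------------------------------------------------

.age_groups <- c("20s", "30s", "40s")

# Total tube length decreases with age within the anatomical 85-105 mm range.
.age_length <- c("20s" = 105, "30s" = 95, "40s" = 85)

# Ciliated-cell density on the mucosal layer, per mm^2, by age group.
.age_cilia_density <- c("20s" = 2000, "30s" = 1600, "40s" = 1400)

# Mucosal fold depth (mm); folds flatten (columnar -> cuboidal epithelium)
# with age, so the perturbation amplitude shrinks.
.age_fold_depth <- c("20s" = 0.15, "30s" = 0.12, "40s" = 0.10)

# Fraction of total length per anatomical region, uterine end first.
# The ampulla share is large enough that four lesions spaced 17 mm apart
# (51 mm end to end) fit inside the ampulla of the shortest (85 mm) tube.
.region_fractions <- c(intramural = 0.08, isthmus = 0.22,
                       ampulla = 0.62, infundibulum = 0.08)

# Resting luminal radius (mm) at region boundaries, uterine end first.
# Chosen so every circular cross-section area lies in 5-40 mm^2.
.region_radii <- c(1.30, 1.45, 1.70, 3.50, 3.40)

.match_age <- function(age_group) {
  if (!is.character(age_group) || length(age_group) != 1L ||
      !(age_group %in% .age_groups)) {
    stop("unknown age group: must be one of ", paste(.age_groups, collapse = ", "))
  }
  age_group
}

#' Build a parametric fallopian-tube model
#'
#' Constructs the reduced-order geometric model of one human fallopian tube:
#' a centerline parameterised by arclength `s` (mm, `s = 0` at the uterine
#' opening of the intramural portion, `s = L` at the infundibulum), four
#' anatomical regions (intramural, isthmus, ampulla, infundibulum) with
#' piecewise-linear resting radii, longitudinal mucosal folds, an
#' age-dependent ciliated-cell density, and (optionally) elliptical
#' endometriosis lesions protruding into the lumen.
#'
#' The canonical endometriosis configuration carries five lesions, each with
#' a 10 x 5 mm footprint: one centred in the isthmus and four placed in the
#' ampulla with consecutive centres exactly 17 mm apart, alternating sides of
#' the tube. Variants with 3, 7 and 10 lesions are also supported.
#'
#' @param age_group One of `"20s"`, `"30s"`, `"40s"`. Sets total length
#'   (105/95/85 mm), cilia density (2000/1600/1400 per mm^2) and fold depth.
#' @param with_endometriosis Logical; if `TRUE` lesions are added.
#' @param lesion_count Number of lesions, one of 0, 3, 5 (canonical), 7, 10.
#' @param overrides Named list of parameter overrides. Recognised names:
#'   `total_length`, `region_fractions`, `region_radii`, `fold_count`,
#'   `fold_depth`, `cilia_density`, `lesion_protrusion_frac`,
#'   `lesion_length`, `lesion_width`, `curvature_amplitude`.
#' @return An object of class `tube_model`.
#' @examples
#' tube <- build_tube("20s", with_endometriosis = TRUE)
#' diff(vapply(tube$lesions[2:5], function(l) l$center_s, numeric(1)))
#' @export
build_tube <- function(age_group, with_endometriosis = FALSE,
                       lesion_count = if (with_endometriosis) 5L else 0L,
                       overrides = list()) {
  age_group <- .match_age(age_group)
  if (!with_endometriosis && lesion_count > 0)
    stop("lesion_count > 0 requires with_endometriosis = TRUE")
  if (!(lesion_count %in% c(0L, 3L, 5L, 7L, 10L)))
    stop("lesion_count must be one of 0, 3, 5, 7, 10")

  ov <- function(name, default) {
    if (!is.null(overrides[[name]])) overrides[[name]] else default
  }

  L <- ov("total_length", unname(.age_length[age_group]))
  if (L < 85 || L > 105)
    stop("total tube length must lie in the anatomical range 85-105 mm")

  frac <- ov("region_fractions", .region_fractions)
  if (abs(sum(frac) - 1) > 1e-12)
    stop("region fractions must sum to 1")
  radii <- ov("region_radii", .region_radii)
  if (any(radii <= 0)) stop("region radii must be positive")

  bounds <- unname(c(0, cumsum(frac)) * L)
  region_names <- c("intramural", "isthmus", "ampulla", "infundibulum")
  regions <- lapply(seq_len(4L), function(i) {
    list(name = region_names[i],
         start_s = bounds[i], end_s = bounds[i + 1L],
         radius_start = radii[i], radius_end = radii[i + 1L],
         fold_count = 12L,
         fold_depth = ov("fold_depth", unname(.age_fold_depth[age_group])))
  })
  names(regions) <- region_names

  lesions <- list()
  if (lesion_count > 0L) {
    lesion_length <- ov("lesion_length", 10)
    lesion_width <- ov("lesion_width", 5)
    centers <- .lesion_centers(lesion_count, regions)
    if (any(centers < 0 | centers > L))
      stop("lesion placed outside the tube [0, L]")
    azimuths <- rep(c(0, pi), length.out = lesion_count)
    lesions <- lapply(seq_len(lesion_count), function(i) {
      list(id = i, center_s = centers[i], azimuth = azimuths[i],
           length = lesion_length, width = lesion_width,
           protrusion_frac = ov("lesion_protrusion_frac", 0.4))
    })
  }

  tube <- structure(
    list(age_group = age_group,
         with_endometriosis = with_endometriosis,
         total_length = L,
         regions = regions,
         lesions = lesions,
         cilia_density = ov("cilia_density",
                            unname(.age_cilia_density[age_group])),
         fold_count = 12L,
         fold_depth = ov("fold_depth", unname(.age_fold_depth[age_group])),
         curvature_amplitude = ov("curvature_amplitude", 0.04)),
    class = "tube_model")
  validate_tube(tube)
  tube
}

# Lesion centre arclengths for each supported lesion count.
# Canonical n = 5: one at the isthmus midpoint, four centred in the ampulla
# with 17 mm consecutive spacing; alternates apply the same pattern scaled.
.lesion_centers <- function(n, regions) {
  isth <- regions$isthmus
  amp <- regions$ampulla
  isth_mid <- (isth$start_s + isth$end_s) / 2
  amp_mid <- (amp$start_s + amp$end_s) / 2
  amp_len <- amp$end_s - amp$start_s
  if (n == 3L) {
    c(isth_mid, amp_mid - 8.5, amp_mid + 8.5)
  } else if (n == 5L) {
    c(isth_mid, amp_mid + c(-25.5, -8.5, 8.5, 25.5))
  } else if (n == 7L) {
    c(isth_mid, amp$start_s + amp_len * (1:6) / 7)
  } else {  # n == 10
    c(isth$start_s + (isth$end_s - isth$start_s) * c(1, 2) / 3,
      amp$start_s + amp_len * (1:8) / 9)
  }
}

#' @export
validate_tube <- function(tube) {
  stopifnot(inherits(tube, "tube_model"))
  L <- tube$total_length
  b <- vapply(tube$regions, function(r) r$start_s, numeric(1))
  e <- vapply(tube$regions, function(r) r$end_s, numeric(1))
  if (abs(b[1]) > 1e-12 || abs(e[4] - L) > 1e-9 ||
      any(abs(e[-4] - b[-1]) > 1e-9))
    stop("regions must tile [0, L] without gaps or overlap")
  if (any(e <= b)) stop("each region must have positive length")
  for (les in tube$lesions) {
    if (les$center_s < 0 || les$center_s > L)
      stop("lesion centre outside the tube")
    if (les$azimuth < 0 || les$azimuth >= 2 * pi)
      stop("lesion azimuth must lie in [0, 2*pi)")
  }
  invisible(tube)
}

# Vectorised resting radius of the lesion-free wall at arclength s (mm),
# ignoring folds: piecewise-linear interpolation of the region radii.
.base_radius <- function(tube, s) {
  b <- vapply(tube$regions, function(r) r$start_s, numeric(1))
  e <- vapply(tube$regions, function(r) r$end_s, numeric(1))
  r0 <- vapply(tube$regions, function(r) r$radius_start, numeric(1))
  r1 <- vapply(tube$regions, function(r) r$radius_end, numeric(1))
  stats::approx(x = c(b, e[4]), y = c(r0, r1[4]), xout = s, rule = 2)$y
}

# Radial encroachment (mm) of lesions at (s, theta); vectorised over s, theta.
# The footprint is elliptical (length along s, width along the circumference);
# the bump profile is a smooth dome with peak `protrusion_frac * base radius`.
.lesion_protrusion <- function(tube, s, theta, base_r) {
  prot <- numeric(length(s))
  for (les in tube$lesions) {
    ds <- (s - les$center_s) / (les$length / 2)
    dth <- atan2(sin(theta - les$azimuth), cos(theta - les$azimuth))
    dw <- (dth * base_r) / (les$width / 2)
    q <- 1 - ds^2 - dw^2
    inside <- q > 0
    if (any(inside)) {
      peak <- les$protrusion_frac * base_r[inside]
      prot[inside] <- pmax(prot[inside], peak * sqrt(q[inside]))
    }
  }
  prot
}

#' Local luminal radius
#'
#' Resting radius of the lumen at arclength `s` and azimuth `theta`:
#' piecewise-linear interpolation of the region radii, plus the sinusoidal
#' mucosal-fold perturbation, minus any lesion protrusion whose elliptical
#' footprint covers `(s, theta)`. Time-dependent wall motion is handled by
#' [wall_displacement()]; `t` is accepted for interface symmetry and ignored
#' here.
#'
#' @param tube A `tube_model`.
#' @param s Arclength (mm), vectorised; must lie in `[0, L]`.
#' @param theta Azimuth (radians), recycled against `s`.
#' @param t Time (s); unused for the resting geometry.
#' @param folds Logical; include the mucosal-fold perturbation (default TRUE).
#' @return Radius in mm, always positive.
#' @export
local_radius <- function(tube, s, theta = 0, t = 0, folds = TRUE) {
  if (any(s < -1e-9 | s > tube$total_length + 1e-9))
    stop("arclength s outside the tube [0, L]")
  n <- max(length(s), length(theta))
  s <- rep_len(s, n); theta <- rep_len(theta, n)
  r <- .base_radius(tube, s)
  if (folds && tube$fold_depth > 0)
    r <- r + tube$fold_depth * cos(tube$fold_count * theta)
  if (length(tube$lesions))
    r <- r - .lesion_protrusion(tube, s, theta, .base_radius(tube, s))
  pmax(r, 0.05 * .base_radius(tube, s))
}

#' Luminal cross-sectional area
#'
#' Open cross-sectional area (mm^2) at arclength `s`, computed by integrating
#' `r(s, theta)^2 / 2` over the azimuth with the trapezoidal rule on a
#' periodic grid (spectrally accurate for the smooth boundary used here).
#'
#' @param tube A `tube_model`.
#' @param s Arclength (mm), vectorised.
#' @param n_theta Number of azimuthal quadrature nodes.
#' @param folds Passed through to [local_radius()].
#' @return Area in mm^2.
#' @export
luminal_area <- function(tube, s, n_theta = 256L, folds = TRUE) {
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  dth <- 2 * pi / n_theta
  vapply(s, function(si) {
    r <- local_radius(tube, rep(si, n_theta), theta, folds = folds)
    sum(r^2 / 2) * dth
  }, numeric(1))
}

# Region containing arclength s; returns the region list element.
region_at <- function(tube, s) {
  for (r in tube$regions) if (s <= r$end_s) return(r)
  tube$regions$infundibulum
}

# Region boundary helpers used by the transport engine.
region_bounds <- function(tube, name) {
  r <- tube$regions[[name]]
  c(r$start_s, r$end_s)
}

#' Centerline curvature profile
#'
#' The intramural and isthmus portions are straight; the ampulla is
#' convoluted, represented as a sinusoidal in-plane curvature with three
#' bends; the infundibulum is straight again. Used for mesh export and
#' trajectory projection; agent dynamics run in the backbone frame
#' `(s, r, theta)` and are unaffected by the centerline shape.
#'
#' @param tube A `tube_model`.
#' @param s Arclength (mm), vectorised.
#' @return Curvature in 1/mm.
#' @export
centerline_curvature <- function(tube, s) {
  a <- region_bounds(tube, "ampulla")
  k <- numeric(length(s))
  in_amp <- s >= a[1] & s <= a[2]
  k[in_amp] <- tube$curvature_amplitude *
    sin(2 * pi * 3 * (s[in_amp] - a[1]) / (a[2] - a[1]))
  k
}

# Planar centerline points (x, y) at arclengths s, by integrating the
# curvature profile on a fine grid.
centerline_points <- function(tube, s) {
  grid <- seq(0, tube$total_length, length.out = 2049L)
  h <- diff(grid[1:2])
  kappa <- centerline_curvature(tube, grid)
  psi <- cumsum(c(0, (kappa[-1] + kappa[-length(kappa)]) / 2 * h))
  x <- cumsum(c(0, (cos(psi[-1]) + cos(psi[-length(psi)])) / 2 * h))
  y <- cumsum(c(0, (sin(psi[-1]) + sin(psi[-length(psi)])) / 2 * h))
  cbind(x = stats::approx(grid, x, s, rule = 2)$y,
        y = stats::approx(grid, y, s, rule = 2)$y,
        psi = stats::approx(grid, psi, s, rule = 2)$y)
}

#' @export
print.tube_model <- function(x, ...) {
  cat("Fallopian tube model (", x$age_group, ", ",
      if (x$with_endometriosis) "tubal endometriosis" else "normal", ")\n",
      sep = "")
  cat("  total length:", x$total_length, "mm\n")
  for (r in x$regions)
    cat(sprintf("  %-13s [%6.2f, %6.2f] mm, radius %.2f -> %.2f mm\n",
                r$name, r$start_s, r$end_s, r$radius_start, r$radius_end))
  cat("  cilia density:", x$cilia_density, "per mm^2\n")
  if (length(x$lesions)) {
    cat("  lesions (", length(x$lesions), "):\n", sep = "")
    for (l in x$lesions)
      cat(sprintf("    #%d  s = %6.2f mm, azimuth %.2f rad, %g x %g mm\n",
                  l$id, l$center_s, l$azimuth, l$length, l$width))
  }
  invisible(x)
}
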