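---
title: "A reduced-order model of gamete transport through normal and endometriosis-affected fallopian tubes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order model of gamete transport through normal and endometriosis-affected fallopian tubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sperm must traverse the fallopian tube from the uterine (intramural) end to
the ampulla, where fertilization occurs; the ovulated oocyte must travel the
opposite way, from the infundibulum to the uterine cavity. Both journeys
depend on the tube's mechanics: peristaltic contractions of the muscular
wall, the coordinated beat of mucosal cilia, the rheology of the luminal
mucus, and — for sperm — flagellar propulsion. Tubal endometriosis places
ectopic lesions on the wall that narrow the lumen and trap passing cells,
and aging degrades ciliary density and wall mechanics. `oviductsim`
estimates how these factors change two outcome statistics: the percentage
of sperm reaching the ampullary fertilization site, and the percentage of
oocytes reaching the uterine cavity, for women in their 20s, 30s and 40s,
with and without endometriosis.

The package is a *reduced-order stochastic simulator*: instead of solving
the Navier–Stokes equations around thousands of deforming cells, it couples
a lubrication-theory flow model to agent dynamics in the tube's backbone
coordinates. This keeps a full 80-hour, 10,000-agent experiment on a
desktop, at the cost of representing the flow and cell mechanics by
calibrated low-dimensional laws. The outcome statistics — not velocity
fields — are the quantities the model is built to reproduce.

## Tube geometry

A tube is a centerline parameterised by arclength $s \in [0, L]$, with
$s = 0$ at the uterine opening. Four regions tile the length in order:
intramural, isthmus, ampulla, infundibulum. Published anatomy constrains
the total length to 85–105 mm and the luminal cross-section to
5–40 mm$^2$; within those bounds we fix $L = 105/95/85$ mm for the
20s/30s/40s groups (tube length declines with age) and split the length
8% / 22% / 62% / 8% across the regions. The ampulla share is chosen so
that four lesions spaced 17 mm apart (51 mm end to end) fit inside the
ampulla of even the shortest tube; an earlier draft split of
10/25/55/10 fails that constraint at $L = 85$ mm. Region radii
interpolate linearly from 1.30 mm at the uterine ostium to 3.50 mm at the
ampullary–infundibular junction, keeping every circular section inside the
5–40 mm$^2$ window. Longitudinal mucosal folds are a sinusoidal radius
perturbation (12 lobes) whose depth shrinks with age (0.15/0.12/0.10 mm),
standing in for the columnar-to-cuboidal change of the epithelium. The
ampullary centerline carries a sinusoidal curvature (three bends) for mesh
export and trajectory projection; agent dynamics live in $(s, r, \theta)$
and are independent of the centerline shape.

Endometriosis lesions are elliptical wall protrusions with the canonical
10 × 5 mm footprint. The five-lesion configuration places one lesion at
the isthmus midpoint and four in the ampulla with centres exactly 17 mm
apart, alternating sides of the tube ($\theta = 0, \pi, 0, \pi, 0$); 3-,
7- and 10-lesion variants are provided. Protrusion depth is not an
anatomical datum; we model it as a fraction of the local resting radius,
default 0.4, exposed as a calibration parameter because it is one of the
levers that controls trapping.

## Wall mechanics and flow

The muscular wall is a compressible neo-Hookean material with energy
$$W = \tfrac{\mu}{2}(I_1 - 3) + \mu \ln J + \tfrac{\lambda}{2}(\ln J)^2,$$
with Lamé parameters obtained from the stiffness $\kappa = 12$–$14$ kPa,
reference length $L$, reference area $A$ and Poisson ratio $\nu = 0.49$:
$$\lambda = \frac{\nu L \kappa}{(1+\nu)(1-2\nu)A}, \qquad
  \mu = \frac{L\kappa}{2A(1+\nu)}.$$
The common compressible neo-Hookean form carries $-\mu \ln J$; this model
uses $+\mu \ln J$, the form adopted here, and the energy is implemented and
tested exactly as written (it is zero at the reference state and positive
nearby for the parameter ranges used). Rather than solving the full
boundary-value problem, the travelling peristaltic pressure wave (20 mmHg,
1.5 min$^{-1}$, i.e. a 40 s period) maps to an inward radial displacement
through a linear compliance $d_0 = c\,p\,R_0/\mu$; two counter-propagating
waves (pro-ovary from the intramural end, pro-uterus from the
infundibulum) superpose, clamped at 90% of the resting radius. The
dimensionless compliance $c$ defaults to 0.2, chosen so that peristalsis
provides oscillatory mixing while the *net* luminal drift is dominated by
the ciliary component — the physiological picture for oocyte transport.
The wavelength is not a printed quantity; it defaults to half the ampulla
length.

The axial flow has two parts. The peristaltic part follows from mass
conservation through the time-varying radius with a closed uterine end
($Q(0,t) = 0$) and a Poiseuille $2(1 - r^2)$ profile; on the axial grid
the identity $\partial Q/\partial s + \partial A/\partial t = 0$ holds to
discretisation tolerance by construction and is tested. The ciliary part
is a near-wall slip velocity
$v_c = c_{\mathrm{cal}}\,\rho\,f\,\ell^2$
($\rho$ = ciliated-cell density 2000/1600/1400 mm$^{-2}$ by age,
$f = 5.4$ Hz, $\ell = 7\ \mu$m a literature-typical cilium length),
directed pro-uterus and decaying linearly to zero at 60% of the radius.
Cilia physiologically beat with an effective stroke toward the uterus;
sperm progress pro-ovary by self-propulsion, not by ciliary carriage. The
single constant $c_{\mathrm{cal}} = 0.003$ folds the stroke efficiency
into the slip law and is set so that a normal 20s oocyte transit completes
in roughly a day and a half, well within the 80 h horizon. Mucus is
isothermal with the affine shear-thinning viscosity
$\eta = 0.02\,\dot\gamma + 0.98$ Pa·s (density 1007 kg m$^{-3}$; the
thermal properties are stored but unused).

## Sperm propulsion

The flagellar beat is generated from 100 dynein motor sites at equal
arclength intervals. Each site contributes curvature proportional to its
sliding force ($2\times10^{-6}\ \mu$N normal,
$5\times10^{-6}\ \mu$N hyperactivated — so the curvature amplitude ratio
is exactly 2.5), travelling as a wave in the beat phase with an
asymmetry offset that is nonzero only in the hyperactivated mode. The 3D
shape integrates the Frenet–Serret system along the flagellum with a small
constant torsion (0.01 $\mu$m$^{-1}$), using exact per-step rotations of
the frame, which preserves orthonormality to machine precision and
arclength to under 0.1%.

Propulsion uses Gray–Hancock resistive force theory: slender-body drag
coefficients on each flagellar segment, bluff-body drag for the head and
midpiece (drag only, no thrust), and a force-free, torque-free solve for
the rigid-body velocity at each beat phase, composed over the cycle. For
small symmetric beats the computed speed matches the classical
small-amplitude formula $(C_n/C_t - 1)\,b^2 k \omega / 2$ to under 5%,
which is the model's independent oracle. The non-printed constants — the
force-to-curvature gain ($5\times10^4\ \mu$m$^{-1}\mu$N$^{-1}$), 1.5
wavelengths on the flagellum, 10 Hz beat, hyperactivated asymmetry offset
0.035 $\mu$m$^{-1}$ — were chosen once so the normal-mode straight-line
speed lands in the physiological 25–50 $\mu$m/s range (about 24 $\mu$m/s
at the defaults, measured over a 1 s window). With these choices the
hyperactivated mode is faster instantaneously but yaws strongly, so its
straight-line progress is *lower* while its lateral excursion is larger —
the behaviour expected of hyperactivation at the fertilization site.
Agents switch to the hyperactivated mode on first entering the ampulla
(configurable to `always`).

## Oocyte transport

The oocyte is a passive sphere: zona pellucida 0.12 mm, corona radiata
0.4 mm, corona shed at 12 h (a single step in effective diameter), and
elasticity 10 ± 5 kPa. It advects at the local flow velocity times a
confined-sphere hindrance $H = (1 - (d/D)^2)^{1.5}$ and rides in a
near-wall radial band ($r/R \in [0.7, 0.9]$), as a settled dense sphere
does, where the ciliary slip acts on it. While the corona is attached the
surface is rougher, doubling the sticking hazard. At lesion-narrowed
sections a squeeze rule applies: passage requires
$d \le D(1 + \varepsilon)$ with $\varepsilon$ inversely proportional to
the elasticity, giving the lesion trapping a mechanical lever. Lesions act
on agents through capture and squeeze; they do not block the bulk flow in
the reduced-order flow solve.

## Transport engine and calibration

Agents advance in $(s, r, \theta)$ with time steps of 1 s (sperm) and
10 s (oocyte); the beat enters only as averaged propulsion, so no
sub-cycling is needed. Wall and lesion sticking are per-second hazards
applied near the wall (sperm) or everywhere (the wall-riding oocyte);
sticking and goal states absorb. A local-density crowding multiplier
(2 mm bins) raises the sticking hazard where agents accumulate, a
desk-scale stand-in for cell-to-cell collision effects at
$n = 10{,}000$. Sperm reach their goal on crossing a threshold at 70% of
the ampulla length; oocytes on crossing $s = 0$. All randomness flows from
one seeded stream with draws in fixed agent order, so identical seed and
configuration reproduce outcomes bitwise.

Four per-age constants are calibrated — the sperm and oocyte wall hazards
against the normal-tube outcome percentages, and the sperm and oocyte
lesion hazards against the endometriosis percentages/reduction rates —
by multiplicative bisection (`scripts/calibrate.R`); the fitted values are
the shipped defaults in `default_params()`. This is the model's stated
operating-point protocol: the reference FEM/CFD internals are not
recoverable, so the printed outcome set defines the calibration targets.
Two reference values are interpolated rather than printed: the 30s
normal-tube oocyte percentage (95%, between the printed 92–98% endpoints)
and the 30s endometriosis percentage (82.5%, between 74% and 91%); the
sperm normal-tube percentages (84/63/33%) are the model's own operating
point, chosen to decrease with age as described qualitatively, since the
reference figures print only the endometriosis reduction rates
(4.8/33.3/81.8%).

## What the simulator does and does not show

The synthetic conditions emulate the study design: 10,000 sperm started
uniformly in the intramural lumen, 100 single-oocyte runs started in the
infundibulum, 80 h horizon, three age groups, five-lesion endometriosis.
They do not emulate patient-specific geometry, mucus heterogeneity,
chemotaxis or capacitation biochemistry, fertilization itself, or the
hydrodynamic interaction between cells; the crowding multiplier is a
statistical surrogate, not a collision model. Passing outcome tests
therefore shows that the calibrated reduced-order mechanism reproduces
the reference statistics under its own assumptions — not that it predicts
an individual tube.

Numerical choices: the axial flow grid has 257 nodes; the azimuthal area
quadrature 256 nodes (spectrally accurate, tested to $10^{-6}$ relative
against $\pi r^2$); wall displacement clamps at 90% of the resting
radius; the Frenet integration uses four substeps per motor interval;
reflecting boundaries handle the wall, the closed uterine end (sperm) and
the fimbrial end. Degenerate inputs (zero-length flagellum, $\nu = 0.5$,
$J \le 0$, oocyte larger than the lumen) raise errors rather than
propagate.

Problem sizes in the shipped tests and acceptance script are the
canonical oocyte design (100 runs × 20 replicates per condition) and a
1,000-agent × 10-replicate sperm design; the full 10,000-sperm experiment
runs in tens of minutes through the CLI and is not required to reproduce
the statistics, which are agent-count-invariant up to binomial error.

## Known limitations

* The flow model conserves mass but not momentum: pressure-driven reflux
  through lesion constrictions is absent, and lesions do not alter the
  bulk flow.
* The $+\mu \ln J$ energy is implemented as adopted; with the reference
  state and parameter ranges used the difference from the $-\mu \ln J$
  form does not enter the transport results (only the compliance scale
  derived from $\mu$ does).
* Oocyte reduction rates reported in the reference literature
  (≈22/30/32%) are inconsistent with the (normal − endo)/normal
  definition applied to the printed percentages; the package computes the
  defined quantity and leaves the discrepancy documented rather than
  guessed at.
* SEM is computed across replicate streams of one RNG; counter-based
  per-agent streams would allow replay of a single agent in isolation,
  which this implementation trades for vectorised speed.
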