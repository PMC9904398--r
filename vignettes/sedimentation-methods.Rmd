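---
title: "Models and methods for active-suspension sedimentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for active-suspension sedimentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activesed)
```

# The physical problem

A suspension of microswimmers under gravity does not behave like a passive
colloid. Thermal fluctuations are negligible at these particle sizes, so a
passive athermal suspension would simply collapse onto the bottom wall;
activity keeps a finite sedimentation length. `activesed` implements three
connected descriptions of this problem and the measurement toolkit that goes
with them:

1. a **dry run-and-tumble model** (`simulate_rtp()`): non-interacting point
   swimmers, the analytic reference;
2. a **resolved-hydrodynamics model** (`simulate_lb()`): finite-size
   squirmers in a lattice-Boltzmann (D3Q19) fluid between no-slip walls;
3. a **steady drift–diffusion model** (`steady_density()`): the Smoluchowski
   equation with a height-dependent effective temperature, which connects
   the two.

## The squirmer

Each swimmer is a sphere of radius $R$ with prescribed tangential surface
slip

$$u_s(\theta) = (B_1 + B_2\cos\theta)\,\sin\theta,$$

where $\theta$ is the polar angle from the orientation $\hat e$. $B_1$ sets
the propulsion speed $v_p = 2B_1/3$; $B_2$ sets the stresslet. The ratio
$\beta = B_2/B_1$ classifies pushers ($\beta<0$, e.g. *E. coli*), pullers
($\beta>0$, e.g. *Chlamydomonas*) and potential swimmers ($\beta=0$);
**shakers** have $B_1 = 0$ ($|\beta|\to\infty$): they stir the fluid without
swimming, with reference speed $v_{B2} = |B_2|/3$, the surface average of the
slip magnitude. This steady slip prescription cannot represent unsteady
flagellar beating; it is meaningful on time scales longer than a beat cycle.

Orientations are randomised at mean interval $\tau$. Two protocols are
provided. `poisson` (the default) draws exponential waiting times and gives
the run-and-tumble diffusivity $D = v_p^2\tau/3$ exactly; `fixed_interval`
tumbles at exact multiples of $\tau$ and gives $D = v_p^2\tau/6$. The
factor-two difference matters when comparing a fitted sedimentation length
against $\lambda = D/(\mu F_g)$, which is why the Poisson protocol — the one
that reproduces $\lambda = \ell^*\chi_1 R/3$ with $\ell^* = v_p\tau/R$ — is
the default; the fixed-interval option is retained and its diffusivity
documented rather than hidden. Similarly, "uniform" tumble angles can mean
uniform on the sphere (`sphere_uniform`, default) or uniform in the polar
angle (`polar_uniform`); both decorrelate runs completely, so all
sedimentation-length results are insensitive to the choice, but the marginal
distribution of $\hat e_z$ differs and orientation statistics are reported
for the sphere-uniform convention unless asked otherwise.

## Dimensionless control parameters

With the passive settling speed $v_g = \mu F_g$, $\mu = 1/(6\pi\eta R)$,
the behaviour is governed by (`dimensionless_groups()`):

* $\chi_1 = v_p/v_g$ — propulsion against gravity. Near $\chi_1 = 1$
  particles pile up at the wall in crystalline layers; for $\chi_1 \gg 1$
  the profile is exponential, $\rho \sim e^{-z/\lambda}$ with
  $\lambda = v_p^2\tau/(3 v_g)$.
* $\chi_2 = \mathrm{sign}(B_2)\, v_{B2}/v_g$ — stresslet activity against
  gravity, the natural control parameter for shakers. The sign convention
  (negative for pushers, positive for pullers) follows the $\beta$
  classification.
* $\beta$, $\ell^* = v_p\tau/R$, $\Gamma = L/H$ (cell aspect ratio).

For *E. coli*-like parameters ($v_p \approx 20\,\mu$m/s, dipole force
0.4 pN over 2 µm in water) these give $|B_2| = f/(\eta\delta) \approx
200\,\mu$m/s, $|\beta| \approx 7$, $\ell^* \approx 25$, and
$\chi_1 \approx 6\text{–}30$ under terrestrial gravity.

# The lattice-Boltzmann engine

The fluid is evolved by a D3Q19 lattice-Boltzmann scheme; swimmers are
resolved spheres coupled by bounce-back-on-links with a boundary-velocity
term containing the rigid motion plus the squirmer slip, and the momentum
exchanged on each link is accumulated into the hydrodynamic force and torque.
Design choices that the physics does not fix, and how they were made:

* **Collision operator**: single-relaxation-time BGK with configurable
  $\tau_{LB}$ (default 1.0, $\nu = c_s^2(\tau_{LB}-1/2)$), chosen for
  transparency; the shear-wave decay test pins the realised viscosity to
  within 1%.
* **Body mass**: neutrally buoyant ($\rho_{body} = \rho_{fluid}$), with
  gravity applied as an external force $F_g$ on each body only, so the fluid
  column itself does not sediment.
* **Cover/uncover**: nodes swallowed by a moving sphere give their mass and
  momentum to the body; uncovered nodes are refilled at equilibrium with the
  local boundary velocity and the neighbour-average density, and the created
  momentum is charged to the body. Both events are book-kept exactly, so the
  mass and momentum budget tests close to floating-point precision rather
  than "approximately".
* **Force smoothing**: hydrodynamic force and torque are averaged over two
  successive steps before entering the Newton–Euler update — the standard
  stabilisation against impulsive cover/uncover noise.
* **Contact guard**: a short-range Hookean repulsion (default stiffness 2,
  onset gap 1 lattice unit) acts between bodies and against the walls. The
  onset is deliberately one full lattice spacing: if a sphere is allowed to
  approach a wall more closely it covers the last fluid layer, the local
  link set degenerates, and the one-sided bounce-back produces a spurious,
  self-amplifying force toward the wall. Keeping one node of fluid in every
  gap avoids this artefact at the cost of a slightly inflated effective
  contact distance; near-wall layer spacings therefore read
  $2R + \mathcal{O}(\text{gap})$, and the layering checks use a stiffer,
  shorter-ranged guard.
* **Effective radius**: a staircase sphere of $R = 2.3$ lattice units does
  not have hydrodynamic radius exactly $R$. `calibrate_r_eff()` measures
  $R_{eff}$ once from Stokes drag on a fixed sphere in a periodically
  forced box, using the periodic-array (Hasimoto) correction
  $F = 6\pi\eta R_{eff}\bar u/(1 - 2.837\,R_{eff}/L)$; drag-based checks are
  quoted against $R_{eff}$.
* **Coordinates**: node centres at half-integers, walls exactly at $z = 0$
  and $z = H$ (half-way bounce-back), gravity along $-z$, bins half-open.
* **Stability limits**: `lb_config()` rejects slip speeds beyond Mach 0.3
  and warns above Mach 0.1; the radius must be at least 2.3 lattice units.

Tumbling reuses the dry engine's event machinery: orientations change
discontinuously at scheduled events while the linear and angular velocities
are left to relax hydrodynamically — legitimate because the run time is kept
much longer than the viscous time $t_\nu = R^2/\nu$ ($\tau/t_\nu \approx 30$
at the default operating point, and $\gtrsim 9$ in the reduced test runs).

# The effective-temperature model

The analogy with the Perrin experiment maps the active suspension onto a
barometric profile at effective temperature $k_B T^{(1p)}_{eff} =
D/\mu$, i.e. an equivalent length $\lambda_{1p} = k_B T^{(1p)}_{eff}/F_g$
(`effective_temperature_1p()`). At strong activity this single-particle
picture fails: hydrodynamic interactions make the fluid a *bath whose
agitation varies with height*. The model promotes the temperature to a
height-dependent field, $T_{eff}(z) = T^{(1p)}_{eff} + T^{(coll)}_{eff}(z)$
with $T^{(coll)}_{eff} \propto \sigma^2(z)$, the slab variance of the fluid
velocity (measured by `lb_fluct_profile()`, with nodes inside bodies
excluded and the slab mean subtracted — the slab-mean convention is a
deliberate choice; subtracting a global mean would fold the mean shear
profile into the "temperature").

The zero-flux steady state of the Smoluchowski equation then gives

$$\rho(z) = C\,\exp\!\left(-\int_0^z \frac{dz'}{\lambda_{eff}(z')}\right),
\qquad
\lambda_{eff}(z) = \begin{cases}
\lambda_{1p}\left(1 + \alpha_1\,\sigma^2(z)/v_p^2\right) & \text{swimmers},\\[4pt]
\alpha_2\,\ell_T\,\sigma^2(z)/v_{B2}^2 & \text{shakers},
\end{cases}$$

with $\alpha_{1,2}$ free proportionality constants fitted by `fit_alpha()`
(least squares on $\ln\rho$). Two conventions needed fixing here:

* the shaker form has no single-particle part ($v_p = 0$), and its
  dimensionless collective temperature must be converted to a length by an
  explicit reference length $\ell_T$; the particle radius is the natural
  choice and the default, and $\ell_T$ is configurable and echoed into all
  outputs because $\alpha_2$ and $\ell_T$ are only jointly identifiable;
* $\lambda_{eff}$ is floored at `floor_eps` ($10^{-6} H$ by default) so that
  shaker dead zones ($\sigma^2 = 0$) yield a finite, flagged, delta-like
  profile instead of NaN.

Numerics: the cumulative integral uses the trapezoid rule on the supplied
grid; the solver agrees with an adaptive-quadrature oracle to better than
$10^{-4}$ relative on smooth profiles at the default resolutions. $\sigma^2$
is interpolated piecewise-linearly and held constant beyond the measured
range (flagged). The fit for $\alpha$ is a 1-D bracketed minimisation,
refined once around the optimum.

The model is *expected* to fail in the supernatant — the distal constant-
density shelf that pullers and $\chi_2 > 0$ shakers develop at large
activity and aspect ratio $\Gamma \ge 1$. That shelf is sustained by a
genuinely three-dimensional, non-local circulation (sediment-driven
pumping), which no local-temperature closure can represent; the comparison
tools let the supernatant region be masked.

# Measurement conventions

* **Steady state** (`detect_steady_state()`): the run is steady over the
  longest final interval on which the mean height $h(t)$ stays within 5% of
  its mean; a minimum window (ten run times by default in the drivers) is
  required. All reported profiles are averages over such windows.
* **Density profiles** (`density_profile()`): half-open bins of width $R/2$
  by default, normalised to $\int\rho\,dz = 1$.
* **Sedimentation length** (`fit_sedimentation_length()`): weighted linear
  fit of $\ln\rho$ vs $z$ (Poisson count weights when counts exist). The
  default window starts at $4R$ — excluding the crystalline near-wall layers
  — and ends at the last bin with at least 10 counts; an $R^2 < 0.9$ flags a
  non-exponential profile, with the value still returned.
* **Layering** (`detect_layering()`): prominence-filtered local maxima below
  $10R$; the spacing of a gravity-dominated sediment reads about one
  particle diameter plus the contact-guard gap.
* **Supernatant** (`supernatant_metrics()`): $\zeta_0$ is the top of the
  occupied region (density above a floor of a tenth of one particle's bin
  weight); the plateau is the distal run of bins with
  $|d\ln\rho/dz|$ below 10% of its occupied-range mean; $X_{sn}$ is the
  particle fraction in the plateau. The flatness criterion is applied to the
  *log*-slope deliberately: a pure exponential has constant log-slope
  $1/\lambda$ and can never qualify (its far tail has a small absolute slope
  and would otherwise be misread as a shelf), while a true supernatant has
  log-slope near zero. An all-uniform profile counts as one big plateau.
* **Orientation statistics** (`orientation_statistics()`): joint histogram
  of elevation and $\hat e_z$ (default 20 orientation bins), normalised as a
  density; conditionals $P(z^*,\hat e_z)/\rho(z^*)$ at requested heights
  (the standard picks are $z^* = 2R$ and $30R$); the polar-order profile
  $m(z) = \langle\hat e_z\rangle_z$. At long run length a sedimenting
  suspension shows $m < 0$ near the wall and $m > 0$ in the bulk — swimmers
  in the bulk preferentially point against gravity.

# What the synthetic generators emulate — and what they do not

`generate_synthetic_sigma2()` produces the three $\sigma^2(z)$ shapes that
cover the phenomenology seen in resolved runs (fluctuations largest inside
the sediment, decaying upward; a constant-background variant; a constant
profile), so the solver and the $\alpha$ fitting can be exercised and
round-trip-tested without any simulation. `sample_from_profile()` inverts a
profile's CDF for fitter round trips. These fixtures are smooth and
noise-free: they do not reproduce the discreteness, the near-wall structure,
or the non-local supernatant physics of a real suspension, so tests passing
on them validate the *solvers and estimators*, not the hydrodynamic claims —
those are checked, at reduced scale, against the lattice-Boltzmann engine
itself.

# Problem sizes used in the shipped checks

The validation suite runs entirely on one CPU. The dry-engine checks use up
to 2000 particles in a $120R$-tall box (the size at which the fitted
$\lambda/(\chi_1 R)$ resolves the theoretical $\ell^*/3$ to a couple of
percent). The lattice-Boltzmann checks run on $16^2\times48$ to $24^3$
lattices with up to 17 resolved squirmers ($\phi = 0.07$), $10^4$–$2\times
10^4$ steps: large enough to show the monotone growth of $\lambda$ with
$\chi_1$, wall accumulation and layering at $\chi_1 \approx 1$, squirmer
self-propulsion at $2B_1/3$, and shaker non-motility, while staying far
below the scales needed to reproduce full suspension phenomenology
(supernatant formation and aspect-ratio sweeps need thousands of particles
and much taller boxes; the package can express those runs, but its shipped
evidence is deliberately reduced-scale).

# Known limitations

* BGK at moderate $\tau_{LB}$ has viscosity-dependent slip errors at
  staircase boundaries; $R_{eff}$ calibration absorbs most of this.
* No lubrication corrections: gaps below one lattice unit are handled by
  the contact guard, not resolved.
* The effective-temperature closure is local by construction and cannot
  describe supernatants (see above).
* The dry engine has no excluded volume: at $\chi_1 \lesssim 1$ it predicts
  wall collapse, not crystalline layers.
* Checkpoints and profiles are plain text (TSV + JSON sidecars); exact
  round-tripping is guaranteed through 17-significant-digit formatting.
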