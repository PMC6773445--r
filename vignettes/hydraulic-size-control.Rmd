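---
title: "Hydraulic size control of the otic vesicle: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydraulic size control of the otic vesicle: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otomorph)
```

The zebrafish otic vesicle grows by inflating itself: epithelial ion
pumps drive fluid into the closed lumen, the lumen pressurizes, and the
pressurized wall stretches, thins and proliferates. This vignette is the
package's own account of the models it implements, the parameters that
matter, the numerical choices behind them, and what the synthetic-data
tests do and do not demonstrate.

## The physical picture

All state variables live on a sphere-equivalent reduction of the vesicle:
a thin shell of average radius $R = (R_o + R_l)/2$ and thickness
$h = R_o - R_l$, where $R_l$ and $R_o$ are the radii of spheres holding
the lumen volume $V_l$ and total vesicle volume $V_o = V_l + V_t$
(`shell_from_volumes()`). Units are µm, hours, Pa and pl throughout
(1 pl = 10³ µm³); viscosities are accepted and reported in Pa·s and
converted to Pa·hr internally.

Four balance laws organize the analysis:

* **Fluid conservation.** $dV_l/dt = S_l \, \Omega$ defines the
  transepithelial flux $\Omega$ (µm/hr). For a sphere this collapses to
  $dR_l/dt = \Omega$, so a near-linear radius trajectory is the signature
  of near-constant flux.
* **Tissue conservation.** $dV_t/dt = j$, with
  $j = s\,dN/dt + N\,ds/dt$: early growth is proliferation offset by
  cell-volume decrease ($j \approx 0$); later growth is proliferation at
  constant cell volume. In the thin-shell limit $V_t \approx 4\pi R^2 h$,
  so conserved tissue forces the wall to thin as the vesicle grows.
* **Surface bookkeeping.** $S_l = \psi N$ (mean apical area × cell
  count) splits surface growth into cell stretching $N\,d\psi/dt$ and
  division $\psi\,dN/dt$; the *break-even time* is where division takes
  over.
* **Force balance.** Laplace's law for a thin pressurized shell,
  $\sigma = PR/2h$, ties lumenal pressure to in-plane wall stress; the
  wall responds as a Maxwell material — elastic (modulus $k$) on short
  time scales, viscous (viscosity $\mu$, $\sigma = 4\mu\dot\varepsilon$
  with $\dot\varepsilon = \dot R/R$) on long ones, with relaxation time
  $\tau = \mu/k$.

Equating the Laplace and Stokes expressions at the measured state gives
the effective-viscosity estimator
$$\mu = \frac{P R^2}{8 h \dot R},$$
implemented in `effective_viscosity()` and applied to interval-averaged
measurements in `viscosity_table()`.

### Error propagation: two formulas, exposed side by side

`propagate_viscosity_error()` offers two modes. `mode = "paper"` is the
published propagation form
$$\frac{\delta\mu}{\mu} = \frac{1}{8}\sqrt{\Big(\frac{\delta P}{P}\Big)^2
 + 2\Big(\frac{\delta R}{R}\Big)^2 + \Big(\frac{\delta h}{h}\Big)^2
 + \Big(\frac{\delta R'}{R'}\Big)^2},$$
which reproduces the published SD table. `mode = "standard"` is the
textbook first-order result for $\mu \propto P R^2 / (h R')$, whose
radius coefficient is 4 and which carries no $1/8$ prefactor. The two
differ by roughly a factor of eight; since the $1/8$ and the coefficient
2 are not what first-order analysis yields for this monomial, neither is
silently "corrected" — the published form is the default because it is
what the published table contains, and the standard form is available
for anyone who wants conventional error bars.

## The feedback growth model

`simulate_vesicle()` integrates the minimal closed-loop model:

* influx with pressure feedback: $\Omega = \Omega_0 - K P$;
* Maxwell wall: $\dot\sigma = 4k\,\dot\varepsilon - \sigma/\tau$;
* Laplace closure: $P = 2h\sigma/R$, with $P \ge 0$ and $P = 0$ while a
  puncture is open;
* tissue conservation: $V_t$ integrates a supplied growth schedule
  $j(t)$ (default: zero before 28 hpf, then 132 pl over 17 h), and the
  shell geometry is recomputed exactly from $(V_l, V_t)$ each step.

In steady growth the stress rides the quasi-static branch and the
pressure satisfies $P^* = \Omega_0 / (K + R^2/(8\mu h))$ — the unique
balance of influx against viscous wall creep. The Maxwell element's
elastic branch matters only transiently: after a puncture (lumen volume
reduced by `loss_fraction`, stress zeroed, barrier resealing after
5 min), pressure rebuilds from zero over the feedback relaxation time,
and while it is low the flux runs near $\Omega_0$ — catch-up growth. The
excess flux is approximately linear in the fractional volume deficit,
which is how the mechanistic closure underwrites the phenomenological
catch-up law $\tilde\Omega - \Omega = \kappa\,\Delta V_l/V_l$.

### Default parameters

| parameter | default | unit | rationale |
| --- | --- | --- | --- |
| $\Omega_0$ | 2.8 | µm/hr | regeneration flux runs 2–5× the wild-type ~1 µm/hr, so the pressure-free influx must sit in that band |
| $K$ | 0.013 | µm/(hr·Pa) | sets $\Omega \approx 1$ µm/hr at $P \approx 140$ Pa |
| $P_0$ | 140 | Pa | homeostatic fixed point implied by $\Omega_0$, $K$ and the 30 hpf geometry |
| $\mu$ | 6.26×10⁶ | Pa·s | the 24–36 hpf effective-viscosity estimate |
| stiffening rate | ln(22.2/6.26)/12 | 1/hr | exponential ramp through the two interval estimates (3.5× over 12 h); applied to $\mu$ and $k$ jointly so $\tau$ is constant |
| $k$ | 200 | Pa | sets the pressure-rebuild time after reseal (~2–3 h) so that a 35% volume loss is recovered with a realized catch-up slope ≈ 4 |
| $\kappa$ | 4 | µm/hr per unit deficit | middle of the observed 3–5 range; also the generator's catch-up gain |

With these defaults the simulated control vesicle holds its flux near
0.8–1.0 µm/hr at 125–165 Pa from 30 to 48 hpf. A known limitation: the
minimal closure does not push the pressure to the ~300 Pa end of the
measured range by 48 hpf while keeping the flux near 1 µm/hr — capturing
both would need an additional regulated quantity (e.g. a rising
$\Omega_0$ or active stiffening beyond the viscosity ramp). The package
reports what the closure produces rather than tuning the trajectory
shape.

The integrator is explicit fixed-step (default dt = 0.005 hr). Two
guards reject unstable configurations: dt must resolve the Maxwell time
($\mathrm{dt} \le \tau/20$) and the stress–pressure feedback rate
$8kKh/R^2 + 1/\tau$. Halving dt changes the final radius by well under
0.1%.

`fit_vesicle_parameters()` wraps the simulator in bounded least squares
on $R(t)$ (plus $P(t)$ when observed, down-weighted ×0.01 so radius
dominates), with residual-resampling bootstrap intervals. Requesting $K$
from an unperturbed, pressure-free trajectory is refused: along the
quasi-static branch $\Omega_0$ and $K$ are nearly collinear, so $K$ is
identifiable only from pressure data or a perturbation.

## The synthetic-data generator

`generate_wildtype_cohort()` draws per-embryo series around smooth
backbone curves — monotone cubic (Fritsch–Carlson) interpolants through
calibration anchors — with additive Gaussian noise whose SD follows the
anchored values, interpolated linearly in time between anchors. Half of
the noise variance is a per-embryo random effect shared across time
points (and shared between the two ears of a paired experiment), half is
independent sampling noise; the published spreads are cross-sectional
SDs over ~10 embryos, so the 50/50 split is a modelling choice, not a
measured one.

Anchor values are the published wild-type numbers: cell count 415 ± 26 →
1106 ± 52; cell volume 0.55 → 0.34 pl by 28 hpf; tissue volume 230.6 pl
then +132 pl; lumen volume ~0 → 440 ± 18 pl; medial/lateral wall 20 →
4 µm with thick poles; pressure 100 → 300 Pa over 30–48 hpf. Interior
anchors that the printed record does not pin down directly — the
mid-growth shape of $N$ and $V_l$, and interior cell-volume values — are
placed so the derived kinetic signatures match the published ones: a
near-constant flux of ~1 µm/hr, near-constant early tissue volume
($N \cdot s \approx V_t$), and a division/stretching break-even near
33 hpf. Two derivations are exact by construction, $V_o = V_l + V_t$
and $\psi = S_l/N$; the surface area has its own (linear) backbone
rather than being tied to the sphere-equivalent lumen radius, because
the published constraints (saturating apical area, linear surface
growth, the printed radius/thickness at 30 hpf) are not mutually
consistent under a strict sphere tie on a non-spherical organ.

What the generator does *not* emulate: non-spherical geometry and
regional flux, left–right developmental asymmetry, segmentation error
structure (noise is Gaussian and independent across quantities),
drop-out, or any active regulation beyond the phenomenological laws
above. Passing tests on these cohorts therefore demonstrates that the
estimators recover what the generating process put in — calibration on
real data is a separate question.

Perturbation designs mirror the published experiments: punctures remove
35% of lumen volume by default (the observed 30–40% drop; the package
treats the printed loss as the *total* of elastic recoil and leakage,
since the two are not separately observable), reseal in 5 min, and
regenerate with excess flux $\kappa \cdot \Delta V_l/V_l$; ouabain and
the Na,K-ATPase morpholino scale influx toward zero with dose;
cytochalasin D raises the realized flux 2–5× by softening the wall
(implemented as a realized-flux factor $1 + 3\,\mathrm{dose}$).

## Numerical and statistical choices

**Derivatives.** All rates come from local least-squares quadratics over
a ±3 h window (7 points at the hourly sampling; `quadratic_window_fit`).
At the series ends the window shrinks one-sidedly and the estimate is
flagged `edge = TRUE`; downstream estimators treat edge points as
lower-confidence. Windows that straddle a puncture are excluded
entirely — a local polynomial is not a valid model across a jump.

**Catch-up regression.** `flux_deficit_regression()` pools post-puncture
(deficit, excess-flux) points across pairs and fits OLS, as the
published analysis does. Two refinements make the estimate usable at
realistic noise: the default half-window is 2 h so the informative
early-recovery points survive the discontinuity exclusion; and a
regression-calibration step projects the noisy deficits onto a common
quadratic trend in time-since-puncture before the final OLS, which
removes the errors-in-variables attenuation that otherwise biases the
slope low by a factor of 2–5. Plain OLS on raw deficits remains
available via `calibrate = FALSE`.

**Break-even time.** On noise-free curves the break-even is the linear
interpolated crossing of the two terms. On noisy cohorts a single local
crossing has hour-scale scatter and occasional spurious early hits, so
the reported estimate is the upward zero-crossing of a quadratic
least-squares fit to the term *difference* over the well-supported
points, falling back to the local crossing (and to `NA`, with a message,
when the terms never cross).

**Plate solver.** The clamped biharmonic problem is discretized with the
13-point stencil on the unit square; the built-in edge condition
$\partial w/\partial n = 0$ enters by ghost-node reflection. The center
coefficient $w_c D / (P L^4)$ converges monotonically to the classical
series value 1.26×10⁻³ (0.5% high at 129²). The printed bending
stiffness "2h²E/3(1−ν²)" equals the classical $Et^3/12(1-\nu^2)$ when
$h$ is read as the half-thickness with its lost exponent restored, so a
single implementation serves both conventions. Displaced volume is the
Riemann sum of the deflection field; by linearity it is computed once at
unit load and scaled.

**Dilution.** The axisymmetric diffusion problem is reduced to a
well-mixed spherical compartment coupled to a quasi-1D variable-area
cone (conservative finite volumes on 360 frustum cells,
Crank–Nicolson, dt = 0.5 s). The reduction is justified by scale
separation: tube efflux, not internal mixing, limits the exchange at
these aspect ratios. Mass balance (vesicle + tube + cumulative efflux)
closes to better than 0.5%, and the radial solver behind
`sphere_dilution_reference()` matches the classical Fourier-series
solution for an absorbing sphere within 1%.

**Plateau extraction.** Traces are smoothed (2 s window), and stages are
segmented on the derivative: a *sustained* (≥2 s) excursion above 5% of
the peak rate opens the rise; the first ≥10 s quiet stretch after it is
the plateau; a sustained drop afterwards is withdrawal. Because a 5%
threshold clips the slow tails of a smooth rise, the plateau and
baseline boundaries are trimmed by a quarter of the detected rise length
before averaging; the reported pressure is plateau mean minus baseline
mean. Flat traces return a zero differential; traces with no detectable
plateau raise an error rather than guessing.

**Determinism.** Every stochastic entry point takes a seed and restores
the global RNG state on exit; identical specs produce byte-identical
cohorts, and `run_pipeline()` is byte-identical under a fixed seed. The
simulator itself is deterministic — seeds govern only noise injection
and bootstrap resampling.

## Problem sizes

The shipped tests and the acceptance script use the study-scale
conditions: cohorts of 10 embryos at hourly sampling, 10 paired puncture
experiments per regression (with 100 pairs across replicates for the
recovery checks), a 129² plate grid, 360 dilution cells over 15
simulated minutes, and simulator runs of 18 h at dt = 0.005 hr. These
sizes are where the estimators' accuracy plateaus on this problem;
larger grids and cohorts change the reported quantities by less than
their tolerances.

## Known limitations

* The spherical-shell reduction ignores the vesicle's mediolateral
  flattening and regional wall heterogeneity except through separate
  thickness series; there is no spatially resolved mechanics.
* The pressure trajectory of the minimal feedback closure flattens near
  165 Pa instead of climbing to ~300 Pa by 48 hpf (see above).
* Material-property estimates from puncture assays are *relative*
  (region vs region); no force calibration exists, so absolute moduli
  are out of reach by design.
* The osmotic side is pure bookkeeping ($M = \Omega c$ at fixed
  isotonic concentration); no ionic species or channel kinetics are
  modelled.
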