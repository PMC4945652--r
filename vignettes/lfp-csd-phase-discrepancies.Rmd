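---
title: "Forward modeling of LFP and CSD phase-patterns: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward modeling of LFP and CSD phase-patterns: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpcsd)
```

This vignette documents the model implemented by `lfpcsd`, the assumptions
behind it, the parameters that matter, the numerical choices made where the
design was genuinely open, and what the simulations can and cannot say
about real recordings.

## The volume-conductor model

Local field potentials are generated by transmembrane currents. On the
mesoscopic scale these are described by a current source density (CSD)
$C(x,y,z)$ — current entering (source, $C>0$) or leaving (sink, $C<0$) the
extracellular medium per unit volume. With a homogeneous, isotropic,
purely resistive medium of infinite extent, the potential solves Poisson's
equation $\sigma \nabla^2 V = -C$, i.e.

$$V(\mathbf r) = \frac{1}{4\pi\sigma}\int
  \frac{C(\mathbf r')}{|\mathbf r - \mathbf r'|}\, dV'.$$

These assumptions (no gray/white-matter contrast, no anisotropy, no
boundaries, ideal point-like electrodes) are the standard starting point
for forward models of intracortical potentials; everything the package
computes inherits them.

The tissue volume is discretized into $K$ cubes on which the CSD is taken
constant, giving the linear forward map $V = GC$ with the $N \times K$
leadfield matrix $G$. Each entry is the *exact* integral of the $1/r$
kernel over a cuboid, evaluated with the analytic corner-sum primitive of
$1/r$ (log/arctan terms). Two numerical points:

* **Field points inside or on a source cube.** The corner-sum formula is
  applied after splitting the cube at the field point into octants, which
  places the (integrable) singularity at a sub-box corner where every
  primitive term vanishes. The potential is therefore finite everywhere,
  including for electrodes lying exactly on cube faces; no special-casing
  or regularization parameter is involved.
* **Cancellation-safe logarithms.** Terms $\log(a + r)$ are evaluated as
  $\log(b^2) - \log(r - a)$ for $a \le 0$ (with $b^2 = r^2 - a^2$), which
  avoids catastrophic cancellation near the primitive's edge lines.

The test suite validates the closed form against an independent adaptive
quadrature oracle (including interior and on-face points) to $10^{-6}$
relative, and against the far-field point-source limit
$V \approx \mathrm{vol}/(4\pi\sigma r)$.

The default study geometry mirrors a Utah-array preparation: an
11.6 mm × 11.6 mm × 3.5 mm volume (the 3.6 mm grid footprint plus 4 mm
margins on each side, so that off-grid sources contribute), with the
10 × 10, 0.4 mm-pitch electrode grid at the intra-laminar center, 1.15 mm
below the tissue top. The electrode plane defines $z = 0$ with $+z$ toward
the pia; "a generator at depth 0.5 mm" therefore means $z_0 = -0.5$. Cubes
are ordered x-fastest, then y, then z with the deepest plane last, so
leadfields are bit-for-bit reproducible.

**Conductivity.** The scalar conductivity $\sigma$ (and the Laplacian's
$\sigma'$) default to 1 S/m. Every phase metric in the package is invariant
to a positive rescaling of $\sigma$ — it scales amplitudes only — so this
choice has no effect on any reported quantity.

## Phasor-level computation

All simulated CSDs oscillate at a single temporal frequency and the medium
is purely resistive, so the temporal factor $e^{i2\pi f t}$ factors out of
the forward map. The package therefore works entirely with complex spatial
phasors at one instant; a time course is recoverable as
$\mathrm{Re}\{\text{phasor}\cdot e^{i2\pi ft}\}$. This is exact, not an
approximation, and makes Monte-Carlo studies cheap.

For separable CSDs $C = C_v(z)\,C_h(x,y)$ the forward map collapses to an
$N \times (n_x n_y)$ operator $H = \sum_z C_v(z)\, G[\cdot, (\cdot, z)]$
(`collapse_leadfield()`), computed plane-by-plane without materializing
$G$; the full matrix (`build_leadfield()`) is available for moderate
resolutions. Experiments at equal geometry share collapsed leadfields
through an in-session cache; tests verify cache on/off equivalence.

## The synthetic CSD families

**Laminar generators.** A generator is a dipolar sink–source pair across
depth: two opposite-sign Gaussian poles of width $\sigma_v$ separated by
the generator length $L$,

$$C_v(z) = A e^{-(z-(z_0+L/2))^2/2\sigma_v^2}
         - (1-\varepsilon) A e^{-(z-(z_0-L/2))^2/2\sigma_v^2}.$$

The imbalance $\varepsilon$ interpolates from a balanced, current-conserving
dipole ($\varepsilon = 0$) through unbalanced ($0.5$) to monopolar ($1$)
sources; imbalance is the phenomenological stand-in for ionic diffusion
currents. The superficial pole (larger $z$) is the positive one, and the
"deep pole" is the one at $z_0 - L/2$. The formula is taken literally:
$\varepsilon = 0$ is balanced — the formula, and the behavior of the
imbalanced simulations, fix the convention. Defaults: $A = 1$ (phase
metrics are amplitude-invariant), $\sigma_v = L/3$ so the poles partially
overlap, $L$ in 0.2–1 mm (the passive dendritic space constant). Multiple
generators superpose with per-generator temporal phase offsets, which is
how inter-laminar phase-differences are represented.

**Intra-laminar waves.** Two families:

* isotropic waves
  $C_h = e^{i\varphi_0} e^{-i2\pi d/\lambda} e^{-d^2/2\sigma_h^2}$, with
  $d$ the distance to the wave center, $\lambda = v/f$, and
  $\sigma_h = \lambda/3$ so a wave is damped out within one wavelength
  (as observed experimentally). Complex fields are built by superposing
  100 such waves with centers uniform over the *full* tissue footprint and
  initial phases uniform on $[0, 2\pi)$. Drawing centers over the full
  11.6 mm footprint (not just the grid) is a deliberate choice: the 4 mm
  margins exist precisely so that off-grid sources contribute
  volume-conducted activity. A seed is mandatory; unseeded stochastic
  fields are refused rather than silently nondeterministic.
* plane waves $C_h = e^{i\varphi_0}e^{i(k_x x + k_y y)}$ with
  $|k| = 2\pi/\lambda$, propagating along $+x$ by default (metrics of
  interest are direction-invariant on the square grid; the direction is a
  parameter).

Both families depend on $(v, f)$ only through $\lambda = v/f$; a property
test verifies that doubling both leaves every phasor field bit-identical.
Canonical band frequencies are 5/10/20/40/80 Hz (theta, alpha, beta, low
and high gamma); plane waves use $v = 0.2$ m/s, isotropic superpositions
$v = 0.1$ m/s.

## Phase metrics

Phases are wrapped to $(-\pi, \pi]$; channels with zero amplitude carry no
phase and are excluded (with a recorded count) rather than propagating
NaNs.

* **Kuramoto order** $r = |\langle e^{i\psi}\rangle|$ over electrodes.
* **Phase gradient**: first-order finite differences of wrapped phase
  steps. Each neighbor difference is wrapped into $(-\pi,\pi]$ *before*
  dividing by the spacing — local unwrapping, which is valid when the
  pitch resolves the wavelength and avoids the path-dependence of global
  2-D unwrapping. At the study's parameters ($\delta = 0.4$ mm,
  $v \ge 0.1$ m/s, $f \le 80$ Hz) the sampling condition holds with a
  wide margin. Central differences are used at interior channels and
  one-sided ones at edges; a forward-only stencil is available as an
  option since the speed estimator averages gradient norms either way.
* **Average propagation speed**
  $\bar v = 2\pi f / \langle\|\nabla\psi\|\rangle$: the channel average is
  taken first, then divided — steep-gradient channels dominate the
  denominator. A vanishing mean gradient (uniform or standing pattern)
  returns `+Inf` with no error, since the short-wavelength limit of the
  forward model genuinely produces standing LFP waves. An alternative
  (averaging per-channel speeds instead) would weight channels
  differently; it is deliberately not implemented because the estimator
  is defined by the formula above.
* **Phase-coherence**
  $\rho = |\langle e^{i(\psi_a-\psi_b)}\rangle|$, invariant to any common
  offset.
* **Phase-contraction** (`phase_between()`): for two positive-amplitude
  sources with phase difference $\psi_{CSD} \in (0,\pi)$ and positive
  weights, the mixed phase lies strictly between the source phases. The
  regime bound is enforced with an error — the theorem is not silently
  extrapolated. The implementation uses the rotated form
  $\xi = 1 + \gamma e^{i\psi_{CSD}}$; tests check it against direct
  numeric evaluation on 1000 random configurations.

When comparing against the CSD, the analytic intra-laminar model is
evaluated *directly at the electrode (or montage-channel) positions* at the
plane $z = 0$, scaled by $C_v(0)$ — not looked up from the nearest cube.
This keeps the reference pattern free of discretization error and carries
the laminar profile's sign at the plane.

## Montages

All montages are linear operators on the complex electrode field:
referential (identity; an ideal infinitely distant reference, with no
reference-electrode noise modeled), average-reference ($v - \bar v$;
exactly annihilates the spatially uniform mode and nothing orthogonal to
it), bipolar (neighbor differences along one axis, proportional to the
directional current density; output channels at pair midpoints — the
physical location of a first-difference estimate, and the location at
which the CSD is evaluated for coherence), and the five-point surface
Laplacian scaled by $-\sigma'$, which estimates the intra-laminar CSD
component when the laminar profile is depth-constant. The Laplacian output
is restricted to the 8 × 8 interior electrodes: boundary stencils would
require extrapolation formulas with no testable ground truth, so they are
simply not produced and downstream metrics use the valid channels.

## Experiments and their problem sizes

Each `run_*` driver is a pure function of (configuration, seed): per-band
realization seeds are drawn once from the master seed, results carry a
complete metadata manifest, and re-execution reproducibility is a tested
contract.

* *Phase-coherence*: per band and imbalance level, seeded 100-wave
  superpositions are forward-modeled and $\rho_{LFP,CSD}$, $r_{LFP}$,
  $r_{CSD}$ recorded per realization.
* *Speed*: plane waves at 0.2 m/s under balanced/unbalanced/monopolar
  generators across the band sweep; optionally the balanced field windowed
  to the grid footprint (hard indicator window by default, a raised-cosine
  taper as an option — the windowing shape is not dictated by the physics,
  only the confinement is).
* *Laminar phase*: superficial (0.25 mm) and deep (1.0 mm) generators of
  common length, a Gaussian intra-laminar amplitude profile
  ($\sigma_h = 1$ mm) with spatially uniform phase (an isotropic wave at
  infinite speed), one recording point at the source center. The deep
  generator's phase is swept over half a cycle for several amplitude
  ratios. The common length defaults to 0.5 mm; the two plausible
  choices at this geometry (0.5 mm and 1 mm) give qualitatively different
  deep/superficial leadfield-weight ratios (about 0.72 vs 1.68), so the
  length is an explicit parameter and both variants are runnable.
* *Montages*: the phase-coherence scenario re-run through all four
  montages, with the coherence reference evaluated at each montage's own
  channel positions; also with a depth-constant laminar profile, the
  regime in which the Laplacian's derivation is exact.

**Resolutions.** The finest supported discretization (204 × 204 × 61,
$K = 2{,}538{,}576$) is expensive and unnecessary for phase metrics. The
package default is 102 × 102 × 30 — chosen so that the halved companion
grid (51 × 51 × 15) nests exactly for convergence testing — and
`leadfield_convergence()` compares LFP phasors of a fixed smooth CSD
against the doubled grid (204 × 204 × 60): at the default resolution the
amplitude change is below 1% and the phase change below 0.01 rad.
Behavioral and invariance tests run on deliberately coarse grids
(16–60 cubes per axis), where the properties under test already hold; the
accuracy-bearing runs (speed fidelity, Laplacian coherence levels) use
102 × 102 × 30 in the acceptance script and 60–102 per axis in the test
suite, with 50 seeded realizations per band for stochastic quantities
(the drivers default to 500 realizations for full-scale runs).

## What the simulations do and do not show

The synthetic families emulate the *spatial statistics* relevant to
volume conduction: laminar dipole structure, intra-laminar wavelength
content, and source imbalance. They do not emulate biophysically detailed
neurons, synaptic receptor distributions, conductance dynamics, broadband
signals (inputs are single-frequency phasors by construction),
measurement noise, electrode impedance, reference-electrode fluctuations,
or conductivity inhomogeneities. Passing tests therefore demonstrate
properties of the idealized forward model — e.g. that LFP phase-patterns
are contracted versions of CSD patterns, or that the Laplacian montage
tracks the intra-laminar CSD — not that any particular experimental
recording satisfies them. In particular, the practical surface-Laplacian
estimators needed for noisy data (spline interpolation schemes) are out of
scope here.

## Known limitations

* The infinite-medium assumption ignores boundaries a few millimeters away
  (white matter, pia, CSF); the 3.5 mm depth extent bounds, but does not
  model, these.
* The two-source phase-contraction theorem applies to positive leadfield
  weights; montaged signals (bipolar, Laplacian) have signed weights and
  can *expand* phase differences — which is precisely why those montages
  change phase-patterns.
* The Kuramoto/coherence metrics treat all valid channels equally; no
  spatial weighting or robust variant is provided.
* The laminar-phase study's informal summary — that the single-point LFP
  phase stays within a tenth of a cycle of the nearer generator — is not a
  theorem: for mixing ratios $\gamma$ near 1 the worst-case deviation
  $\arcsin(\min(\gamma, 1/\gamma))$ exceeds that bound, and the test suite
  records the measured maximum honestly.
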