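---
title: "Modelling interstitial fluid load support in cartilage creep tribology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling interstitial fluid load support in cartilage creep tribology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartifls)
```

## The problem

Articular cartilage is a fluid-saturated porous tissue. Under a step
compressive load the interstitial fluid pressurises and carries most of
the load; as the fluid slowly drains, load transfers to the solid
matrix, the tissue creeps, and friction rises. The fraction of the
applied load carried by fluid pressure — the interstitial fluid load
support, IFLS = average pore pressure / nominal contact pressure — is
the mechanistic link between tissue composition, creep strain, and the
coefficient of friction (COF). `cartifls` implements the complete
computational chain needed to study that link in cartilage-on-cartilage
creep tribology:

1. an axisymmetric fibril-reinforced poroviscoelastic finite-element
   model of unconfined creep, from which IFLS is extracted;
2. identification of the five specimen-specific material parameters
   from a measured creep curve;
3. tribo-rheometer signal processing (lift-off exclusion, torque
   smoothing, COF, Hersey numbers) and the strain-IFLS, COF-IFLS and
   Stribeck analyses;
4. nonparametric group statistics; and
5. a synthetic-experiment generator that emulates the four-group study
   design (healthy / enzymatically degraded tissue, saline / bovine
   synovial fluid lubricant) so the full pipeline is testable without
   access to laboratory data.

## Constitutive model

The solid skeleton is split into a tension-only collagen fibril network
and an isotropic nonfibrillar (proteoglycan) matrix; interstitial flow
follows Darcy's law. Five parameters are specimen-specific: the
nonfibrillar modulus $E_{nf}$, the initial and strain-dependent fibril
network moduli $E_f^0$ and $E_f^\varepsilon$ (network tangent modulus
$E_f^0 + E_f^\varepsilon\,\varepsilon_f$), the initial permeability
$k_0$, and the permeability exponent $M$. Three constants are fixed:
fibril damping $\eta = 947$ MPa s, nonfibrillar Poisson's ratio
$\nu = 0.47$, and initial void ratio $e_0 = 3.5$ (a 78% water
fraction).

Because the source literature states the ingredients but not one
canonical set of equations, the package adopts the following concrete,
independently testable laws:

* **Nonfibrillar matrix** — compressible Neo-Hookean,
  $\sigma = \tfrac{\mu_s}{J}(B - I) + \tfrac{\lambda_s}{J}\ln J\, I$,
  which reduces to isotropic linear elasticity $(E_{nf}, \nu)$ at small
  strain (verified to 1% at strain $10^{-3}$).
* **Fibrils** — for each direction, the logarithmic strain of the
  material line element loads an equilibrium spring
  $\sigma_{eq}(\varepsilon) = E_f^0\varepsilon +
  \tfrac12 E_f^\varepsilon \varepsilon^2$ in parallel with one Maxwell
  branch sharing the same strain-dependent tangent modulus and damping
  $\eta$. The 1:1 stiffness split between the two branches is a
  documented choice; the source formulation does not pin it down.
* **Permeability** — $k = k_0 J^M$, equivalently
  $k_0\!\left(\frac{1+e}{1+e_0}\right)^M$ with $1+e = J(1+e_0)$.

**Fibril geometry.** The network is homogeneous: primary fibrils lie
parallel to the articular surface (unit vectors $e_r$ and $e_\theta$),
secondary fibrils cover seven directions approximating isotropy, with a
3:1 primary:secondary density ratio (exposed as a parameter). Weights
are normalised so the assembled network's uniaxial tangent stiffness
along a primary direction at zero strain equals $E_f^0$ exactly; the
test suite confirms this for several density ratios. Out-of-plane shear
components cancel over the direction set's $\pm$ pairs, so the network
stress stays axisymmetric.

**Two numerical choices deserve emphasis.**

* *Overstress integration.* The Maxwell branch ODE is integrated with
  its exact exponential map over each step (constant strain rate,
  tangent frozen at the end-of-step strain) rather than backward Euler.
  With creep steps growing geometrically to hundreds of seconds while
  the fibril relaxation time $\eta/E_{tan}$ is of order 100 s, a
  first-order update produced several-percent displacement errors that
  violated the package's own time-step-refinement invariant; the
  exponential map restores first-order-small, refinement-convergent
  errors and is exact for the standard-linear-solid limit.
* *Tension gate regularisation.* A tension-only fibril cannot push, so
  the total fibril stress (spring + overstress) is floored at zero, and
  recruitment is smoothed over a $10^{-4}$ strain window (fibril
  uncrimping). Without the floor, a rapidly unloading fibril crosses
  the gate carrying finite dashpot stress, the residual becomes
  discontinuous, and Newton's method limit-cycles.

## Finite-element solver

The two articulating plugs are modelled as one axisymmetric layer of
averaged thickness (radius 3.5 mm) under a constant nominal stress of
0.78 MPa applied through an impermeable, rigid, frictionless platen.
The default mesh is 60 x 40 = 2,400 bilinear
displacement--pore-pressure quadrilaterals; a 15 x 10 coarse mesh is
the fitting workhorse (a mesh-doubling test bounds the final-strain
difference at 0.5%).

Boundary conditions: cartilage-bone interface fixed and impermeable;
outer edge traction-free and freely draining ($p = 0$); symmetry axis
with no radial motion and no flow; platen impermeable, all contact
nodes sharing a single axial degree of freedom with free radial slip.
No contact algorithm is used — full contact from the start is assumed
and contact pressure is defined as load/area. The load ramps linearly
over 0.5 s (the physical test loads at 1 mm/s, reaching the target
stress within a fraction of a second) and is then held.

The coupled finite-strain Biot equations (total stress = fibril +
Neo-Hookean effective stress $- pI$; Darcy flux with $k(J)$; fluid
continuity) are integrated with backward Euler on a geometrically
growing step (0.05 s growing by 1.15x, capped at 250 s), Newton
iteration with element-level finite-difference Jacobians assembled into
a banded matrix, two-sided equilibration (the momentum and continuity
blocks differ by many orders of magnitude in SI units), LAPACK banded
factorisation with the shared platen degree of freedom handled as a
bordered row/column, and adaptive step halving on non-convergence.
A modified-Newton scheme reuses each factorisation until the residual
reduction stalls.

Equal-order u/p pairs need pressure stabilisation; the package uses a
local pressure-projection term acting on the *rate* of the
intra-element pressure fluctuation (artificial storage
$\alpha/\mu_s\,\partial\tilde p/\partial t$ with $\alpha = 0.05$,
halvable in the options). Acting on the rate matters: a non-rate
variant injects an artificial volume source each step and does not
converge under time-step refinement. The term is conservation-neutral
(its test-space contraction vanishes elementwise).

**IFLS extraction.** POR is the average pore pressure over the model
domain (volume average; 2 x 2 Gauss quadrature of the bilinear field),
and IFLS = POR / nominal stress. A contact-surface area average is
available as an option. The volume average was adopted as the default
because it is the literal reading of "average pore pressure extracted
from the model" and because, under the package's default healthy
parameters, it reproduces the published strain-IFLS regression
(slope $-0.29$, intercept $0.33$, linear $R^2 \ge 0.99$) where the
surface average does not (slope $-0.28$, $R^2 \approx 0.978$). The
same convention-selection logic fixes the Hersey number's
load-per-unit-length at $W/(2 r_{eff})$: it is the only candidate that
reproduces all four published values ($8.1\cdot10^{-10}$ to
$2.4\cdot10^{-8}$) with the synovial-fluid viscosity.

**Verification.** In the no-fibril, small-strain limit (and with the
bottom surface allowed frictionless slip to match the classical
boundary conditions) the solver agrees with the closed-form Bessel
series for linear biphasic unconfined creep to better than 0.5% on the
coarse mesh over $[10\,\mathrm{s}, 2.5\,t_{gel}]$; the series itself is
verified against an independent radial finite-difference consolidation
solver (0.5%), and its instantaneous ($\sigma_0/3\mu_s$) and drained
($\sigma_0/E_s$) limits are exact. The physical configuration keeps the
bone interface fully fixed; the slip option exists only for this
comparison.

## Parameter identification

`fit_parameters()` minimises the RMSE between the simulated layer
displacement and `model_share` (default 0.5) of the measured pair
displacement on the experimental grid. The optimiser is bounded
derivative-free simplex search in transformed coordinates: moduli and
permeability in $\log_{10}$ space (their plausible ranges span
decades), each wrapped by a logit onto the search box
($E_{nf} \in [0.01, 5]$, $E_f^0 \in [0, 20]$,
$E_f^\varepsilon \in [0, 1000]$ MPa, $k_0 \in [10^{-16}, 10^{-13}]$
m$^4$/(N s), $M \in [0, 15]$). All Latin-hypercube starts are screened
with one evaluation; the best are polished by repeated Nelder-Mead
restarts (a single simplex run stalls reliably in this correlated
5-parameter space) until improvement stalls, an RMSE tolerance is
reached, or the evaluation cap is spent. RMSE weighting is uniform on
the supplied grid; callers control the effective weighting through the
grid itself (the analysis drivers use log-spaced subsamples of the
10 Hz record, which balances ramp, transient and equilibrium
information).

Identifiability hinges on sampling the load ramp. With a fitting grid
that starts after the ramp, the split between $E_f^0$ and
$E_f^\varepsilon$ is nearly unidentifiable — a local minimum with
$E_f^0 \approx 0$ and inflated $E_f^\varepsilon$ reproduces the creep
curve to ~0.5 um RMSE and attracts both simplex and damped
least-squares refinement. Adding a handful of samples from the ramp
phase (0.1-0.5 s), where fibril strains are still small and $E_f^0$
controls the stiffness, makes noiseless self-recovery exact (RMSE at
machine precision, all five parameters recovered). The fitting drivers
and tests therefore always include ramp samples. The
$\nu$-sensitivity sweep (0.15, 0.37, 0.47, all other parameters held)
shifts the magnitude and dissipation rate of IFLS while preserving the
displacement trend, mirroring the published sensitivity analysis.

## Tribology pipeline

* **Lift-off exclusion** — intervals where axial force drops below 20%
  of the nominal load for at least 5 s, padded by a 2 s guard band
  (thresholds configurable); a record with more than half its samples
  excluded is rejected.
* **Torque smoothing** — 10 s centred moving average on the stitched
  signal, window shrinking at the ends.
* **COF** — $\mu = \tfrac32 |\tau| / (N r)$ for annular rotational
  contact.
* **Kinematics** — effective radius $r_{eff} = \tfrac23 r$ (the
  area-averaged tangential speed of a rotating circular contact), so
  36, 108, 360 and 1080 deg/s give 1.5, 4.4, 15 and 44 mm/s; Hersey
  number = velocity x viscosity / (load per unit length).
* **Pairing and regression** — model and record clocks are both zeroed
  at load onset; model IFLS and strain are interpolated onto the 10 Hz
  grid of retained samples and fitted by ordinary least squares
  ($\mu = \mu_{IFLS}\cdot\mathrm{IFLS} + \mu_0$, and strain vs IFLS
  whose intercept is the maximum strain at zero fluid support,
  $\varepsilon(0)$). $R^2$ is defined as 0 for constant responses.
* **Stribeck surface** — each velocity's regression line evaluated on
  an IFLS grid and interpolated linearly across $\log_{10}$ Hersey.
* **Statistics** — Kolmogorov-Smirnov normality screen, Kruskal-Wallis
  across groups (slowest velocity excluded by default, mirroring the
  study protocol), Friedman across velocity blocks within samples,
  Pearson correlation of $E_{nf}$ with $\mu_0$ and $\mu_{IFLS}$.

## Synthetic experiments

The generator emulates the study design: four groups x three specimen
pairs x four velocities, 10,000 s holds sampled at 10 Hz, alternating
$\pm6$-revolution blocks (18, 124, 180, 516 rotations at the four
velocities) each followed by a 10 s lift-off. Parameters are log-normal
around group medians (healthy: $E_{nf} = 0.3$, $E_f^0 = 2$,
$E_f^\varepsilon = 100$ MPa, $k_0 = 2\times10^{-15}$ m$^4$/(N s),
$M = 5$ — typical bovine femoral-condyle values for this model family;
degraded: stiffnesses divided by three and $k_0$ tripled, matching the
reported up-to-threefold change; dispersion $\sigma_{\log} = 0.25$,
a plausible between-animal scatter, since the published per-group
values appear only graphically). Ground-truth friction follows
$\mu = \mu_{IFLS}\cdot \mathrm{IFLS} + \mu_0$ per group (healthy-saline
uses $-0.15$ and $0.11$), with a $+0.03\,\mathrm{IFLS}^2$ term for
degraded groups reproducing their extra nonlinearity, floored at zero
because a linear law extrapolates negative at very high IFLS while
physical friction cannot be (the flag marking floored samples is kept
with the record's ground truth). Torque is synthesised by inverting the
COF formula with the instantaneous noisy force, so the pipeline
recovers the generating law exactly in the noiseless case. Noise
defaults: displacement 2 um, torque $2\times10^{-4}$ N m (well inside
the 0.15 N m cell range), force 0.05 N. One global seed derives
per-record substreams deterministically.

What the generator does **not** emulate: rehydration mechanics during
lift-offs (the force gap is inserted, the model keeps creeping),
shear-driven transient flow, curved or incongruent surfaces,
depth-dependent composition, and swelling. Passing tests therefore
demonstrate the pipeline's internal consistency and statistical
calibration — not that the model captures those physical effects in
real tissue.

## Problem sizes and degenerate inputs

The test suite and the acceptance script run everything at desk scale:
the 15 x 10 fitting mesh, holds of 600-18,000 s, capped optimiser
budgets, and cohort layouts with shortened holds. These sizes are
stated in the scripts themselves. Degenerate inputs are handled
explicitly: non-positive volume ratios raise degenerate-deformation
errors, inverted elements poison the residual and trigger step halving,
constant regressors raise degenerate-design errors, fully tied Friedman
blocks report a zero statistic, and groups with fewer than two samples
are skipped with a log entry.

## Known limitations

* The concrete constitutive equations (Neo-Hookean variant, 1:1
  equilibrium/Maxwell split, $k_0 J^M$) are one member of the published
  model family; fitted parameters are model-dependent bulk descriptors,
  not intrinsic tissue properties.
* The tied rigid-platen condition assumes full congruent contact from
  the start; migrating or partial contact is out of scope.
* Torsional shear is not modelled inside the FE solver; IFLS during
  articulated creep inherits that simplification.
* Lift-off rehydration is not simulated; the temporal IFLS profile
  between blocks is therefore smoother than in the experiment.
* With three pairs per group (the study's n), group contrasts appear
  as trends; the statistical-power test in the suite shows the same
  contrasts become significant at n = 20.
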