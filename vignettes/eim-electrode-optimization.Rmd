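---
title: "Modelling tetrapolar EIM and optimizing electrode placement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tetrapolar EIM and optimizing electrode placement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

Electrical impedance myography (EIM) injects a weak alternating current
through an outer pair of surface electrodes and reads the potential
difference across an inner pair; the transfer impedance
$Z = \Delta V_{\mathrm{sense}} / I_{\mathrm{drive}} = R + jX$ and its
derived quantities (phase, conductance $G = R/(R^2+X^2)$, capacitance
$C = X/((R^2+X^2)\,\omega)$) track the electrical state of the underlying
muscle. The clinical difficulty is that the same reading also shifts with
anatomy — muscle bulk, subcutaneous fat — and with the electrode layout
itself. `eimsim` simulates this measurement on an idealized limb and
searches for the tetrapolar layout whose 50 kHz reactance is least
sensitive to muscle-thickness variation while still separating atrophied
from normal muscle.

## The forward model

The upper arm is modelled as concentric cylinders of fixed length
146 mm: bone marrow, cortical bone, muscle and a merged
skin/subcutaneous-fat shell. Muscle is anisotropic (longitudinal
conductivity along the limb axis exceeds transverse); all other layers
are isotropic. Within the quasi-static approximation the potential obeys

$$\nabla \cdot \left( \gamma \nabla V \right) = 0, \qquad
\gamma = \sigma + j \omega \varepsilon_0 \varepsilon_r,$$

with $\gamma$ tensor-valued in muscle. Drive electrodes are perfectly
conducting potential surfaces (1 V and grounded); sense electrodes are
floating equipotential surfaces constrained to zero net current; every
other boundary is insulating. No contact impedance or interelectrode
capacitance is modelled.

Because "muscle thickness" is anatomically ambiguous, two conventions
are supported; the default reads the quoted value as the *outer
diameter* of the muscle layer, which makes the 41–56 mm study range
correspond to a 51–66 mm arm — anatomically plausible — with the
per-side annular reading available as an option. Bone geometry is not
specified by any printed value, so marrow (7 mm) and cortical bone
(12 mm outer radius) defaults are documented assumptions. Axial
electrode spacings are read edge-to-edge; this convention is pinned by
an internal consistency check: the optimized layout's gaps
(33-7-33 mm with 7 mm sense electrodes) imply a drive inner-edge
separation of $2\cdot33 + 2\cdot7 + 7 = 87$ mm, exactly the separation
quoted for it. An electrode quoted as "65 mm × 7 mm" is read as 65 mm
of circumferential arc by 7 mm axially — the only reading that fits a
146 mm limb once 60 mm of gaps are present.

### Sign convention

The solver works with the physical admittivity
$\gamma = \sigma + j\omega\varepsilon_0\varepsilon_r$, under which a
capacitive tissue yields $\mathrm{Im}(Z) < 0$. Reported quantities
follow the EIM literature's positive-reactance convention:
$X = -\mathrm{Im}(Z) \ge 0$, $C = X/((R^2+X^2)\omega) \ge 0$, phase
$\theta = \mathrm{atan2}(X, R) \ge 0$. All statements such as
"reactance decreases with muscle thickness" are in this convention.

## Synthetic tissue dielectrics

No dielectric table is shipped with the study this package models; the
values come from literature surveys and animal data that are not
printed. The `tissue_models` stage therefore *generates* them from
Cole–Cole dispersions,

$$\varepsilon^*(\omega) = \varepsilon_\infty +
\sum_k \frac{\Delta\varepsilon_k}{1 + (j\omega\tau_k)^{1-\alpha_k}} +
\frac{\sigma_s}{j\omega\varepsilon_0},$$

the standard parameterization of measured tissue spectra: it is smooth,
positive, and produces the expected monotonicities (effective
conductivity non-decreasing, permittivity non-increasing in frequency).
Default constants were chosen once, for physiological plausibility in
the 1–500 kHz band, before any acceptance quantity was computed:
muscle transverse conductivity ~0.3 S/m with a strong beta-type
dispersion centred near 100 kHz; skin-fat, cortical bone and marrow one
to two orders of magnitude less conductive with weaker dispersions near
20 kHz. Muscle anisotropy is a single ratio (default 3) applied
multiplicatively, so the longitudinal/transverse conductivity ratio is
exact at every frequency. Atrophy multiplies muscle conductivity by 0.5
and permittivity by 0.6 — the modelled study quantifies atrophy only as
"distinguishable", so these are free parameters of the generator.
`perturb_library()` applies seeded unit-mean lognormal factors to probe
robustness of conclusions to these unknown constants.

What the generator does *not* emulate: temperature dependence,
inter-subject variability in non-muscle tissues, frequency-dependent
anisotropy ratios, and any absolute calibration against measured human
spectra. Passing tests therefore validate the *mechanics* of the
pipeline and the *qualitative* physics (trends, orderings,
discriminability), not agreement with any individual's measured
impedance.

## Discretization and linear algebra

The solver uses node-centred finite volumes on a structured cylindrical
tensor grid $(r, \theta, z)$. Every layer radius and every electrode
patch edge is a grid surface by construction, so material coefficients
are single-valued on control-volume faces and patch node sets are
exact. The $r = 0$ axis is a single shared node per $z$-plane with
area-weighted closure fluxes (no singular equation). Angular fluxes use
the exact $\int \gamma/r\,dr$ weight across each two-material strip;
axial fluxes use the annular area split at the node radius.

The current density is singular at electrode patch edges
(Dirichlet-to-insulating transitions), which would limit the observed
convergence of $Z$ to roughly first order on uniform grids. Grid lines
are therefore graded toward patch edges (cubic clustering in $z$ and
$\theta$, and radially toward the outer surface), which restores an
empirical order near 2 on the homogeneous verification case.

Each frequency yields a complex-symmetric system $K = A + jB$ with $A$
the conduction part (symmetric positive definite) and $B$ the
displacement part. $A$ is factorized once per solve with a sparse
Cholesky decomposition and used as the preconditioner for a COCG
(conjugate-orthogonal CG) iteration on $K$; the preconditioned spectrum
is $\{1 + j\,\tan\delta\}$ with $\tan\delta$ the tissue loss tangents,
so convergence to a $10^{-12}$ relative residual typically takes well
under ten iterations. A block-real sparse LU of
$\begin{pmatrix} A & -B \\ B & A\end{pmatrix}$ is the automatic
fallback. When the medium has zero permittivity the system is real and
is solved directly, so the purely-resistive limit returns
$X = 0$ exactly. Floating sense electrodes are implemented by
collapsing their surface nodes onto one master unknown, which enforces
the equipotential and zero-net-current conditions simultaneously and
keeps the system symmetric; drive current is recovered by summing
discrete edge fluxes, which coincides with the energy bilinear form and
is therefore adjoint-consistent. Discrete reciprocity (drive/sense
exchange) and charge conservation hold to solver precision and are
asserted at $10^{-8}$ and $10^{-10}$ respectively.

Mesh presets target cell sizes of (3 mm, 30°, 10 mm) for `coarse`,
(1.8 mm, 15°, 5 mm) for `medium` and (1 mm, 9°, 2.8 mm) for `fine` in
$(r, \theta, z)$; a typical limb mesh has ~4–6k nodes at coarse and
~16–25k at medium. Electrode patches are always resolved by at least
two cells per surface direction (patches below 0.2 mm are refused).

## Verification oracles

Every sensitivity or optimization run is gated by a cached oracle
suite: (1) the homogeneous cylinder with full-ring electrodes must
reproduce $R = d/(\sigma \pi a^2)$ within 2% (the oracle geometry keeps
drive-to-sense distance at twice the radius so the uniform-field
closed form is valid, and uses narrow 2 mm sense rings so their
shunting is negligible at the 50 mm centre separation); (2) reciprocity
below $10^{-8}$; (3) conservation below $10^{-10}$. A Richardson
refinement study on the same case estimates the empirical convergence
order and extrapolates a reference impedance; the layered isotropic
variant must agree with its own extrapolation within 2% at
mid-resolution.

## Sensitivity statistic and experiments

For a thickness sweep $\{t_i\}$ (defaults: muscle
$\{41, 46, 51, 56\}$ mm at fixed 5 mm fat; fat $\{3, 5, 7, 9\}$ mm at
fixed 51 mm muscle — grids that bracket every printed value of the
modelled study), the package computes the per-step change
$(v_{i+1} - v_i)/(t_{i+1} - t_i)$ and the ordinary least-squares slope
of the parameter against thickness. The magnitude of the slope of
$X(50\,\mathrm{kHz})$ versus muscle thickness is the optimization
fitness; the sign is not meaningful (the aim is a flat response).
Configuration comparisons report
$100 \cdot (|s_{\mathrm{conv}}| - |s_{\mathrm{cand}}|)/|s_{\mathrm{conv}}|$.

## Genetic algorithm

Four variables: drive and sense angular halfwidths (3–90° per side of
the symmetry plane) and the sense-sense and sense-drive edge-to-edge
gaps (3–33 mm). Operators follow the named classical set: stochastic
uniform selection over rank-scaled expectations ($\propto
1/\sqrt{\mathrm{rank}}$, a documented choice — the selection method is
defined over scaled expectations but no scaling is named in the
modelled study), arithmetic (convex) crossover with a single uniform
weight per mating, adaptive feasible mutation (uniform direction,
step = fraction of the bound range, expanded ×1.5 after improving
generations, contracted ×0.5 otherwise, floored at 0.02 so exploration
survives flat landscapes), elitism of 2, crossover fraction 0.8.
Stopping: 100 generations or 50 stalled generations at a $10^{-6}$
tolerance (neither is specified by the modelled study; these mirror
common defaults). Elitism makes the best-so-far fitness exactly
non-increasing, which is asserted on every history.

Desk-scale runs (population 20, ≤30 generations, coarse mesh, three
seeds, 3-point thickness grid) are used by the tests and the
acceptance script; the full population-100 configuration is available
through `ga_config()`. The GA fitness uses the coarse mesh; reported
best individuals can be re-scored on the medium mesh.

### What the optimizer actually finds

The gap variables converge robustly to the corner the modelled study
reports: sense-sense gap at its 3 mm lower bound, sense-drive gap at
its 33 mm upper bound — drives as far apart as allowed, senses close
together, implying a drive inner-edge separation of
$2\cdot33 + 2\cdot7 + 3 = 83$ mm (the study quotes 87 mm with a 7 mm
sense gap). The angular-coverage variables behave differently in this
model: the absolute-slope fitness is nearly flat in them (about
0.056–0.067 Ω/mm across the whole 3–90° range at the gap optimum) with
a slight preference for *wide* electrodes, because a wider floating
sense patch shunts more current, lowering the baseline reactance and
with it the absolute slope. The modelled study reports the opposite
(6° angular coverage optimal). The discrepancy is a scale effect of
the absolute-slope criterion interacting with unknown tissue
constants: configurations with smaller baseline $X$ get smaller
absolute slopes almost for free, and which lever (smaller electrodes
or wider shunting ones) minimizes baseline $X$ depends on the
dielectric data. A slope normalized by the baseline reactance would
remove this scale advantage, but the study defines the fitness as the
absolute slope, so that is what is implemented. At the conventional
spacing, where the gaps are fixed, the model does reproduce the
study's electrode-area claim: 1 mm × 1 mm "point" electrodes give a
smaller muscle-thickness slope than the 65 mm × 7 mm rectangles.

## Numerical choices and degenerate inputs

* Iterative solve tolerance $10^{-12}$ (relative residual), 500
  iteration cap, direct fallback on non-convergence.
* Constant (degenerate) sweep responses yield slope 0 with an
  undefined correlation, reported as `NA` rather than an error.
* A zero baseline slope makes a percent reduction undefined; this is
  an error, not a silent `Inf`.
* Individuals whose electrode footprint cannot be placed score
  `Inf` and are ranked worst; non-finite fitness values warn and are
  ranked worst rather than aborting a run.
* Ties in SUS ranks use average ranks, so an all-equal population is
  selected exactly uniformly.
* Reruns with identical configurations are bit-identical, including
  CSV artifacts (fixed 17-digit formatting); every artifact carries an
  FNV-1a hash of its configuration.

## Problem sizes used by the shipped runs

The analysis drivers, tests and the acceptance script run at desk
scale, chosen as the smallest sizes at which every qualitative claim is
stable across a mesh level: coarse meshes (~4–6k nodes) for sweeps,
trends and the GA; the medium mesh (~16–25k nodes) for the
closed-form gate and the reported slope anchors; population 20 with at
most 30 generations and three seeds for the optimization. The
conclusions reproduced this way are orderings and reductions, which
stabilize at far smaller problem sizes than absolute impedances do.

## Known limitations

* Tissue constants are synthetic stand-ins; absolute impedances and
  absolute slopes carry their uncertainty (the slope *orderings* are
  the robust outputs).
* The cylinder idealizes the arm; no MRI-derived geometry.
* Electrode-skin contact impedance is excluded by design, which makes
  floating-electrode shunting stronger than it would be with a real
  contact layer — directly relevant to the angular-variable finding
  above.
* Sense patches are floating equipotentials; a point-probe mode
  (1 mm × 1 mm patches) is provided for comparison but true
  zero-area probes are not modelled.
* No measurement noise model: the study itself defers noise analysis,
  and the lower signal amplitudes of the optimized layout would make
  noise robustness the next question to ask.
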