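# eimsim

Simulation workbench for **electrical impedance myography (EIM)**
electrode design. EIM assesses muscle health by injecting a weak
alternating current through an outer electrode pair on the skin and
reading the voltage across an inner pair; the tetrapolar transfer
impedance `Z = ΔV/I = R + jX` shifts with disease, but also with
anatomy (muscle bulk, subcutaneous fat) and with the electrode layout
itself. This package reproduces, as a tested in-silico pipeline, the
study design in which a finite-element-style forward model of the upper
arm is combined with a genetic algorithm to find the electrode
configuration whose **reactance at 50 kHz** is least sensitive to
muscle-thickness variation while still discriminating atrophied from
normal muscle.

What it contains:

* **Synthetic tissue dielectrics** — Cole–Cole dispersions
  `ε*(ω) = ε∞ + Σ Δε/(1+(jωτ)^(1−α)) + σs/(jωε0)` for marrow, cortical
  bone, anisotropic muscle (longitudinal/transverse) and a merged
  skin-fat layer, for a normal and an atrophied condition, standing in
  for literature data that the modelled study used but did not print.
* **Forward solver** — node-centred finite volumes on a conforming
  cylindrical tensor grid for `∇·((σ + jωε0εr)∇V) = 0` on a
  four-layer limb (146 mm long), with drive electrodes as Dirichlet
  potential surfaces, sense electrodes as floating zero-net-current
  equipotentials, and insulating boundaries elsewhere. Complex solves
  use a sparse-Cholesky-preconditioned COCG iteration.
* **Verification oracles** — closed-form homogeneous-cylinder gate
  `R = d/(σπa²)`, Richardson refinement study (empirical order ≈ 2),
  reciprocity (< 1e-8) and charge conservation (< 1e-10); every
  experiment refuses to run unless the gates pass.
* **Sensitivity pipeline** — muscle sweeps {41, 46, 51, 56} mm and fat
  sweeps {3, 5, 7, 9} mm, per-step changes `(vᵢ₊₁−vᵢ)/(tᵢ₊₁−tᵢ)`, OLS
  slopes of R or X at 50 kHz against thickness, configuration
  comparisons `100·(|s_conv|−|s_cand|)/|s_conv|`, and normal-vs-atrophied
  discrimination.
* **Genetic algorithm** — stochastic uniform selection, arithmetic
  crossover, adaptive feasible mutation, elitism (2), crossover
  fraction 0.8, over four variables: drive/sense angular halfwidths
  (3–90° per side) and the two axial gaps (3–33 mm), minimizing
  |slope of X(50 kHz) vs muscle thickness|.

Named electrode presets: `conventional` (15-30-15 mm gaps,
65 mm × 7 mm electrodes), `optimized` (33-7-33 mm, 7 mm × 7 mm),
`wide` (44-2-44 mm, 1 mm × 1 mm) and `point` (conventional gaps,
1 mm × 1 mm).

## Worked example

Compare the conventional and optimized layouts by the slope of the
50 kHz reactance against muscle thickness (coarse mesh; the oracle
gate runs automatically first):

```r
library(eimsim)
lib <- make_tissue_library("normal")
cmp <- compare_configs(electrode_preset("conventional"),
                       electrode_preset("optimized"),
                       lib, "muscle", c(41, 46, 51, 56), "X", 5e4)
cmp$slope_a
#> <sensitivity_result> X @ 50 kHz vs muscle thickness [conventional]
#>   slope -0.2584 ohm/mm, intercept 18.76 ohm, r -0.9820
cmp$slope_b
#> <sensitivity_result> X @ 50 kHz vs muscle thickness [optimized]
#>   slope -0.09302 ohm/mm, intercept 7.072 ohm, r -0.9798
cmp$reduction_percent
#> [1] 63.9957
```

Reading: under the conventional layout the 50 kHz reactance drops by
about 0.26 Ω for every millimetre of extra muscle diameter — an
anatomical confounder for diagnosis. The optimized layout (drives far
apart, senses close together, small electrodes) cuts that sensitivity
by about two thirds, while `disease_discrimination()` confirms it still
separates an atrophied muscle (reduced conductivity/permittivity) from
a normal one by far more than the 5% flag threshold at 50 kHz.

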