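---
title: "Models and methods behind flowspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flowspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowspec)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters and their defaults,
what the synthetic-data generators do and do not emulate, and the numerical
choices made where the design was genuinely open.

## The measurement principle

A microbead is anchored to a coverslip by a single dsDNA tether and loaded
by fluid drag. Because the analysis chip consists of *serially connected*
rectangular channels of common height `h` and different widths `w`, one
volumetric flow rate `Q` traverses them all, the mean velocity in channel
`i` is `V_i = Q/(w_i h)`, and both the drag force and the force loading
rate scale as `1/w_i`. A single linear inlet ramp `Q(t) = Q0 + βt` thus
loads different channels at different, simultaneously observed rates
(`channel_force_scale()`, `mean_velocity()`).

Force is not computed from first-principles hydrodynamics. It is
*calibrated*: the transverse fluctuations of a tethered bead behave like an
inverted pendulum of arm `l + r` (tether extension plus bead radius), so
equipartition gives

$$F = \frac{k_B T (l + r)}{\langle \delta y^2 \rangle},$$

and per-velocity force estimates are fit to the empirical linear law
`F = c V` (`equipartition_force()`, `fit_calibration()`). The pendulum arm
comes from the flow-parallel swing `d` of the bead when flow is applied:
`(l + r)² = d² + r²`, which assumes negligible vertical displacement — an
assumption the package inherits and does not test.

### Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `thermal_energy` | pN nm | 4.114 | room temperature; every formula uses it |
| `viscosity` | Pa s | 1.0e-3 | water; only sets simulator correlation times |
| calibration slope `c` | pN s/mm | fit from data | geometry-specific, must be re-fit if bead radius, tether length or channel height change |
| `displacement_threshold_um` | µm | 2.0 | tethered-bead selection; strict inequality, flow-parallel component only |
| `area_floor_fraction` | — | 0.5 | rupture call; robust to partial-frame blur, unlike a literal zero-area rule |
| `upsample_factor` | — | `ceiling(pixel_size/10)` | registration resolution ≈ pixel/factor, targeting ~10 nm |
| `n_terms` | — | 50 | series CDF truncation |
| `n_floor` | — | 20 | minimum ruptures per CDF fit |
| `n_groups` | — | 3 | subgroup statistics |

The default thermal energy is stated as an energy rather than a
temperature: supplying `temperature` instead derives `thermal_energy`
through the Boltzmann constant, so the two can never disagree.

## The rupture model

For a slip bond loaded at constant rate $\dot F$, with reduced parameters
$a_1 = k_{off}/\dot F$ and $a_2 = \Delta X/k_B T$:

$$p(F) = a_1 e^{a_2 F} \exp\!\Big[\tfrac{a_1}{a_2}\big(1 - e^{a_2 F}\big)\Big],
\qquad
P(F) = 1 - \exp\!\Big[\tfrac{a_1}{a_2}\big(1 - e^{a_2 F}\big)\Big],$$

and the density's mode is the most probable rupture force

$$F^* = \frac{k_B T}{\Delta X}\,
  \ln\frac{\dot F\,\Delta X}{N\,k_B T\,k_{off}},$$

where $N$ identical bonds loaded in series rupture $N$-fold faster,
shifting $F^*$ down by $(k_B T/\Delta X)\ln N$.

Numerical choices:

* The density is evaluated in log space; at forces where
  $e^{a_2 F}$ is astronomically large the log density is $-\infty$ and the
  density correctly underflows to zero rather than overflowing.
* Two CDF evaluations are provided. The **exact** closed form above is the
  default: it is a true CDF (0 at F = 0, tending to 1). The **series**
  form truncates $\sum_{n\ge1} a_1^n/(n!\,a_2^n)e^{n a_2 F}$ at
  `n_terms = 50`, each term evaluated as
  $n\ln(a_1/a_2) + n a_2 F - \ln n!$ under a log-sum-exp, because the raw
  terms overflow near 40 pN. Its converged limit exceeds the exact form by
  the constant $e^{a_1/a_2} - 1$ (the series omits the $n = 0$ term),
  about 0.4% at antigen–antibody-scale parameters; the tests assert this
  identity. Whether published fits of this family of CDFs used the series
  or the exact integral is generally not knowable; both are exposed and
  agree on fitted $\Delta X$ to better than 2%.
* $F^*$ with a log argument at or below 1 (near-equilibrium loading) is
  returned as a flagged non-positive value with a warning rather than an
  error, because CDF fitting may legitimately wander through that region.
* Sampling uses the exact inverse CDF,
  $F = a_2^{-1}\ln[1 - (a_2/a_1)\ln(1-u)]$, via `log1p` on both
  logarithms.

## The fitting pipeline

"Binned cumulatively" is ambiguous, so the default empirical CDF is the
loss-free one: sorted forces at plotting positions $i/n$, ties sharing the
highest position of their run; a fixed-width binned variant exists for
fidelity. Per-rate fits minimize the sum of squared differences between
the model CDF and these positions over $(\log_{10} k_{off}, \Delta X)$
with a bounded quasi-Newton optimizer (bounds $k_{off} \in [10^{-12},
10^3]$ s⁻¹, $\Delta X \in [0.01, 100]$ nm; solutions pinning a bound
warn). Initialization exploits two Bell-model identities:
$\Delta X_0 = k_B T/\mathrm{SD}(F)$ and $k_{off,0}$ from inverting the
$F^*$ formula at the sample mode (kernel density argmax). On noiseless
quantile data the fit recovers parameters to optimizer precision
(asserted at $10^{-4}$ relative).

Per-condition uncertainty follows the random-subgroup rule: the rupture
population is split without replacement into three near-equal groups, each
refit, and $F^*$ reported as mean ± SD. The global landscape comes from
ordinary least squares of $F^*$ on $\ln\dot F$ — slope $s$ gives
$\Delta X = k_B T/s$, intercept $b$ gives
$k_{off} = \Delta X/(N k_B T)\,e^{-b/s}$ — with uncertainties propagated
from the regression covariance by the delta method. Unweighted OLS is the
default; a `1/SD²`-weighted variant is available, and the serial-bond count
`N` is always a user declaration (3 for a doubly-biotinylated tether
between streptavidin surfaces, 1 otherwise), never inferred. Censored
beads (no rupture by ramp end) are excluded from CDF fitting with a logged
count; the model offers no censoring-aware likelihood here.

## Worm-like chain

The Marko–Siggia interpolation formula

$$F = \frac{k_B T}{P}\Big[\frac{1}{4(1 - l/L_c)^2} - \frac14 +
  \frac{l}{L_c}\Big]$$

is the standard choice for dsDNA at the sub-10 pN forces of a
flow-stretching assay; the extensible (stretch-modulus) variant is omitted
because enthalpic stretching is negligible below ~10 pN. Fitting is
nonlinear least squares **in extension** — force is the controlled
variable here, extension the measured one — against the numerical inverse
of the force law (bisection to $10^{-12}$ relative; the inverse pair is
tested to $10^{-9}$). Bounds: $P \in [1, 500]$ nm,
$L_c \in [1.001\,l_{max}, 10\,l_{max}]$. When several beads are measured,
the averaged force–extension curve is fit (the per-bead fits remain
available by mapping `fit_wlc()`), matching the averaged-curve reading of
how multi-bead force–extension data is usually reported.

## Sub-pixel tracking

Displacement between a bead window and its frame-zero reference window is
the peak of the Fourier cross-correlation. The integer-pixel peak of the
plain inverse transform is refined on an upsampled grid evaluated *only*
in a ±0.75-pixel neighbourhood of the coarse peak, using a
matrix-multiply DFT — mathematically identical to zero-padding the FFT
product by the upsampling factor and reading the dense peak, at a small
fraction of the cost. The tests assert this equivalence to $10^{-6}$ px
against the brute-force zero-padded oracle. The default upsampling factor
targets ~10 nm resolution (`ceiling(pixel_size_nm / 10)`).

Coordinate convention: images are row-major with origin top-left, `x` is
the column index, `y` the row; positions convert to µm via the pixel size;
the flow axis defaults to `+x`.

Tethered-bead selection uses the flow-parallel excursion from the first
frame under each of two opposite flows, requiring strictly more than
2.0 µm in *both*; stuck beads fail the threshold and beads present in only
one direction's tracks are treated as free-floating and rejected (a strict
mode errors instead). Rupture is the first frame whose in-window area
falls below half the bead's initial (first-five-frame median) area — a
literal area-of-zero rule is fragile when the last visible frame is
partially blurred — and the ramp flow rate at that frame is the rupture
flow rate; beads that never drop out are right-censored at the final rate.

## Kinetics under constant force

Bead removal during a constant-force hold mixes two independent
single-exponential processes: anchor dissociation (background, rate `k_b`)
and toehold-mediated strand displacement (rate `k_s`). Independence makes
the total rate additive, so the displacement rate is recovered by
subtracting the invader-free background fit from the invader-present fit.
The subtraction is implemented as total-minus-background (the physically
meaningful, non-negative direction); noise-driven negative differences are
clipped to zero with a warning. Each rate is the censored-exponential
maximum-likelihood estimate, events over total observed time, with the
chi-square event-count confidence interval; single-rate kinetics per
condition is an explicit modelling assumption (no multi-exponential
fitting).

## What the generators emulate — and what they do not

* `simulate_tethered_bead()` is an Ornstein–Uhlenbeck process with
  stiffness `F/(l + r)`, free-space Stokes drag `6πηr` (water, no wall
  correction), and an *exact* discretization, so the equilibrium variance
  `kBT(l + r)/F` holds for any step size and the equipartition estimator
  is exercised without discretization bias. Drag only sets the correlation
  time, not the equilibrium variance, so the missing wall correction
  cannot bias force estimates — it only rescales how long a record must be.
  Records start from an equilibrium draw; `fluctuation_variance()` still
  supports a burn-in for records that do not. Sampling below twice the
  Lorentzian corner frequency `κ/(2πγ)` attaches an aliasing warning,
  mirroring why real calibrations are done below ~1 pN.
* `render_bead_movie()` draws soft-edged disks (1-px Gaussian edge) or
  Gaussian spots at sub-pixel centers with additive Gaussian noise — enough
  structure for threshold detection and sub-pixel registration, with no
  attempt at real transmitted-light optics (no interference rings, shading
  or depth effects).
* `simulate_rupture_experiment()` derives per-channel loading rates
  `c·β/(w h)` from the ramp and calibration, samples rupture forces by the
  exact inverse CDF and converts them back to rupture flow rates,
  right-censoring at ramp end. Vertical lift forces, Poiseuille profiles
  and bead–wall interactions are not modelled.
* `simulate_survival()` draws competing exponentials with right-censoring
  at the observation horizon.

Passing tests on this synthetic data therefore demonstrates that the
*analysis* is correct under the stated statistical model; it does not
validate the physical assumptions (wall effects, tether heterogeneity,
non-exponential kinetics) that real data may violate.

## Problem sizes and reproducibility

The validation suite uses the sizes a desk-scale replication calls for:
2000 rupture forces per loading rate (three rates, three replicates) for
antigen–antibody-scale landscape recovery, 500 beads per channel on a
four-channel chip across three ramps (twelve rates spanning 0.01–10 pN/s)
for the DNA-unzipping-scale recovery, nine noisy force–extension curves of
20 points for the worm-like-chain refit, and 20 fluctuation records per
velocity at four velocities (each ~220 relaxation times long, 25 Hz) for
the calibration slope. Every stochastic step takes an explicit seed;
`run_pipeline()` expands a single scenario seed into per-stage seeds by a
fixed offset scheme so stages are individually reproducible, and repeated
runs of the same scenario are byte-identical.

## Known limitations

* Bell-model (Evans–Ritchie) kinetics only: no beyond-Bell rupture models,
  rebinding, or near-equilibrium corrections — hence the flagged-value
  contract on `F*` at very low loading rates.
* The rupture CDF fit is least-squares on the empirical CDF, not maximum
  likelihood; censored beads are dropped from that fit rather than
  modelled.
* No drift correction or 3-D (z) tracking; off-plane bead motion is
  assumed negligible, consistent with the in-plane geometry relation.
* The per-rate `(k_off, ΔX)` pairs from single-rate CDF fits are strongly
  correlated along the Bell manifold; only the multi-rate global
  regression pins the landscape. This is a property of the model family,
  not of the implementation.
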