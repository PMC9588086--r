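---
title: "Transport, mixing and dose-response methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transport, mixing and dose-response methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcggtools)
```

`mcggtools` models the computational chain behind a hydrogel-based
microfluidic drug-screening device: a tree-like microfluidic
concentration gradient generator (MCGG) feeds an array of
membrane-capped microwells holding hydrogel-encapsulated cells, and the
questions that decide whether the screen is interpretable are
quantitative ones — does the mixer fully mix at the operating flow rate,
what dilution ladder does the channel network deliver, how fast does a
drug cross the channel and penetrate the gel, and what EC50 do the
viability data imply. This vignette describes each model, its
assumptions, the tunable parameters, and the choices made where the
design was genuinely open.

## Stokes–Einstein transport chain

Small molecules are treated as hard spheres. From molecular weight $MW$
(g/mol) and bulk density $\rho$ (g/cm³), the molar volume gives the
hydrodynamic radius

$$r = \left(\frac{3\,MW}{4\pi N_A \rho}\right)^{1/3},$$

the Stokes–Einstein relation gives the diffusivity $D = k_B T / (6 \pi
\mu r)$, and the one-dimensional diffusion time across a channel of
width $x$ is $t = x^2 / (2D)$. Constructors accept the field-standard
units (g/mol, g/cm³) and convert once at the boundary; everything
internal is SI (m, s, K, Pa·s).

**Viscosity calibration.** The default conditions are $T = 310.15$ K
(37 °C, the incubation temperature) with $\mu = 1.01\times10^{-3}$
Pa·s. That viscosity is water near 20 °C, not 37 °C — the pairing is
deliberate: it is the unique viscosity that reproduces the published
diffusivity/crossing-time table for this panel to 3 significant
figures, so we adopt it as the package default and leave both values
user-overridable. With the true 37 °C viscosity
($\approx 6.9\times10^{-4}$ Pa·s) every $D$ would be ~46% higher.

Four of the eighteen published table cells do not reproduce from the
printed inputs at 3 significant figures no matter the viscosity: the
carmustine radius (and hence its $D$ and $t$) is only consistent with a
density of ~1.69 g/cm³ where 1.7 is printed, and the lomustine radius
computes to 4.0449×10⁻¹⁰ m — a value sitting on the 3-significant-figure
rounding boundary that the source apparently double-rounded upward to
4.05×10⁻¹⁰. The package reports full
precision and documents rather than patches the discrepancy.

```{r}
transport_table(study_molecules())[, c(1, 4:6)]
```

## Mixing quantification

A cross-width intensity profile is extracted from a channel micrograph
as the column means of one color plane over a rectangular ROI (the
"Plot Profile" operation), normalized so the undiluted-dye reference
maps to 1 and the chip background to 0. Two metrics summarize it:

* the **absolute mixing index**, the population coefficient of
  variation $AMI = \sqrt{\tfrac1N\sum_i (I_i - \langle I\rangle)^2} /
  \langle I \rangle$, which is 0 for a perfectly mixed (flat) profile
  and scale-invariant in the intensities; and
* the **profile slope**, the ordinary least-squares slope of intensity
  vs position, 0 at complete mixing. The signed slope is the default
  (its sign carries which inlet is which); an absolute-value switch is
  provided.

Population (divide-by-$N$) rather than sample standard deviation is
used, matching the index's definition. Normalization references are
explicit arguments rather than auto-detected extremes, because the dye
plateau and background are measured once per imaging session and reused
across a series; auto-scaling each image would silently re-zero a
partially mixed profile.

ROI conventions are 1-based inclusive row/column ranges — the native
indexing of R matrices and of the imaging packages this code sits on —
rather than 0-based half-open intervals. End-of-mixer dilution fractions
are estimated by linear interpolation of mean channel intensities
between the designated 100% and 0% channels, which makes the estimate
exactly invariant to affine intensity transforms (illumination gain and
offset).

## Dilution-network model

The gradient generator sets its dilution ladder by channel *width*
rather than length: merging streams combine as the flow-weighted mean
$c_{out} = \sum q_i c_i / \sum q_i$, and for channels of equal length
and height the hydraulic conductance — and hence $q$ — is approximately
proportional to width. Under that heuristic the reconstructed two-stage
topology (150/150 µm for the ½ rung, 50/150 µm for the ¼ rung) yields
exactly $(1, \tfrac12, \tfrac14, 0)$. The printed feed-width lists do
not uniquely determine the interior routing (in particular the role of
the 75 µm channel), so the shipped topology
(`inst/extdata/width_ladder_network.yaml`) is an example configuration
consistent with the design intent, not a hard-coded schematic. For
networks with known segment lengths, `rectangular_resistance()`
provides the exact rectangular-duct series solution (parallel-plate
limit within 1% for $w \gtrsim 10h$; square-duct factor 28.45 at 10+
series terms) so that weights can be conductances instead of widths.

## FCS triplet model

The autocorrelation of a single diffusing species through a 3-D
Gaussian confocal volume, with a reversible dark (triplet) state, is

$$G(\tau) = \frac{1}{N}\,
  \frac{1}{1+\tau/\tau_D}\,
  \frac{1}{\sqrt{1 + p^2\,\tau/\tau_D}}
  \left(1 + \frac{T}{1-T}e^{-\tau/\tau_T}\right),$$

with $N$ the mean particle number, $\tau_D$ the diffusion time, $p =
r_0/z_0$ the focal aspect constant, and $T, \tau_T$ the triplet
amplitude and lifetime. The axial factor is written with $p^2$ — the
standard 3-D Gaussian result. Some sources print the same factor with a
bare $p$; since $p$ is usually fixed from calibration rather than
fitted, the two conventions differ only by a fixed reparameterization,
but both are exposed (`p_squared = FALSE`) and tested so either
convention can be matched exactly.

Fitting is Levenberg–Marquardt least squares (**minpack.lm**) with
box bounds enforcing the parameter invariants ($N, \tau_D, \tau_T > 0$,
$0 \le T < 1$) instead of penalty terms, unweighted by default (an
optional $1/G^2$ weighting approximates relative error). Starting
values are data-driven: $N \approx 1/G(\tau_0)$ and $\tau_D$ from the
half-decay lag. A fitted $\tau_D$ converts to a diffusivity through the
calibrated focal radius, $D = r_0^2/(4\tau_D)$, and
`calibrate_confocal_volume()` is its exact inverse. On synthetic curves
with 2% multiplicative noise and 50 log-spaced lags over four decades,
the median $\tau_D$ error is below 5% (typically ~2%).

## Drug penetration

Drug entering the 250 µm hydrogel from the perfusion stream is modelled
by the semi-infinite constant-surface-concentration solution of Fick's
second law, $c(x,t) = c_0\,(1-\mathrm{erf}(x/2\sqrt{Dt}))$. The
semi-infinite form is retained even though the gel is a finite slab —
it is conservative at the far boundary (a reflecting bottom would only
speed equilibration) and is the form the screening analysis used. The
boundary concentration is a free parameter so the same model covers the
2 mM and 10 µM drug cases. `time_to_threshold()` inverts the solution
by bracketing `uniroot` on $\log t$ around the diffusive scale
$x^2/4D$ (the solution is strictly increasing in $t$, so the root is
unique); the closed-form inversion through the inverse error function
is used as an independent oracle in the tests.

With the measured in-gel diffusivity of $2.55\times10^{-10}$ m²/s, the
gel bottom reaches 85% of a 2 mM surface concentration after 1 h and
95% after ~8.7 h. Published prose for the same scenario states sharper
bounds (>95% within 1 h) that direct evaluation of the erf model does
not reproduce at this depth; those bounds are therefore treated as a
documented discrepancy, not as targets.

## Dose–response

Viability is the live fraction of counted cells in percent. The
dose–response curve is a Hill-type sigmoid on *linear* concentration,
$V(c) = b + (t - b)/(1 + (c/EC_{50})^h)$, rather than a log-dose 4PL,
because the measured designs include a true zero-dose control that the
linear form evaluates exactly at the top plateau (a log-dose mode is
available for positive-dose designs). Default constraints keep the
plateaus physical ($b \ge 0$, $t \le 100$). $R^2$ is computed on the
untransformed viability scale. Fitting the measured mean viabilities of
the inert-gel TMZ screen gives an EC50 near 0.8 mM with free plateaus —
within the 0.5–1 mM bracket expected for these data; the exact value is
model-form dependent, which is why published point EC50s are treated as
soft brackets. When comparing conditions whose residual viabilities
differ (the adhesive vs inert gel), the free bottom plateau absorbs
part of the difference; pinning the floor at zero compares potency on a
common scale (see `analysis/06_dose_response.R`).

## Synthetic data: what it does and does not emulate

Every generator is a pure function of its parameters and seed and
returns its ground truth, so all analysis stages have closed-loop
recovery tests with no external data.

* **Mixing images** encode a cross-width interdiffusion profile —
  the erf kernel at residence time $L/v$ — linearly into the blue plane
  of an RGB image (exercising the blue-channel extraction path), with
  Gaussian pixel noise (default SD 0.01 on a [0,1] scale, a typical
  quiet-camera level). They deliberately omit what a serpentine channel
  adds: transverse Dean/turn advection, depth averaging, and uneven
  illumination. Consequently absolute AMI values are conservative
  (higher than a real serpentine mixer achieves at the same residence
  time); monotone trends and the linear flow-rate dependence are the
  meaningful outputs.
* **Cell images** place non-overlapping bright disks in two planes
  (live/dead). Non-overlap is the default because the counting workflow
  being emulated assumes resolvable cells; the threshold +
  connected-components counter (4-connectivity labelling via
  **EBImage**; the generated disks are disjoint, so 4- vs
  8-connectivity cannot change a count) then recovers the exact truth,
  which is the point: the end-to-end test asserts 90/10 counts return
  exactly 90% viability. No point-spread function, bleaching or
  clumping is simulated.
* **FCS curves** apply multiplicative Gaussian noise to the model
  (default 2%, the level at which commercial correlators typically
  operate over minutes of acquisition); real correlator noise is
  lag-correlated, which this does not reproduce.
* **Dose–response tables** add Gaussian noise in viability percentage
  points (default 5 pp in the recovery studies, matching the replicate
  SDs of the measured tables) and clamp to [0, 100].

Passing recovery tests on these generators shows the estimators are
correct and well-conditioned at realistic noise; it does not validate
robustness to the optical artifacts real micrographs carry.

## Numerical choices and problem sizes

* Error functions are evaluated through the normal CDF
  (`2*pnorm(x*sqrt(2)) - 1`), accurate to machine precision over the
  needed range.
* All simulation studies in the tests and analysis scripts use fixed
  seeds; recovery studies use 50–100 replicate curves/tables, mixing
  series use five flow rates at 192×48 px — sizes at which the full
  suite completes in seconds while medians are stable to well inside
  the asserted margins.
* Degenerate inputs fail loudly: zero mean intensity (AMI), equal
  normalization references, zero-contrast dilution references, constant
  viability tables, non-bracketable thresholds and invalid parameters
  all raise informative errors rather than returning NaN.

## Known limitations

* The transport chain assumes spherical molecules and a single scalar
  viscosity; no shape corrections or temperature-dependent viscosity
  models.
* The dilution network is a steady-state, rigid-channel model: no CFD,
  startup transients, compliance, or membrane permeation.
* FCS fitting covers a single diffusing component; no multi-component
  or anomalous-diffusion models, and no computation of $G(\tau)$ from
  raw photon traces.
* Penetration ignores reaction–diffusion (cellular drug consumption),
  membrane resistance and convection in the perfusion layer.
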