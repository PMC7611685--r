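---
title: "Modelling radiation-induced plasmid DNA damage kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling radiation-induced plasmid DNA damage kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidkin)
```

## The assay and the model

A supercoiled plasmid (for example pBR322) is a sensitive, cell-free DNA
damage dosimeter. A single-strand break (SSB) anywhere on the circle releases
the supercoiling and produces the relaxed, open-circular form; a double-strand
break (DSB) — in practice usually two closely spaced SSBs on opposite strands
— produces the linear form. The three topologies separate on a native agarose
gel, so the fractions of supercoiled (S), relaxed (R) and linear (L) DNA in a
lane summarize the damage state of the sample.

`plasmidkin` models topology conversion as two consecutive irreversible
first-order steps,

$$S \xrightarrow{k_{sr}} R \xrightarrow{k_{rl}} L,$$

indexed by an exposure variable $x$ that is absorbed dose $D$ (Gy) for an
external beam, or incubation time $t$ (h) for a radionuclide co-incubated at
fixed activity. The master equations integrate to

$$S(x) = S_0 e^{-k_{sr}x}, \qquad
R(x) = S_0 \frac{k_{sr}}{k_{rl}-k_{sr}}\left(e^{-k_{sr}x} - e^{-k_{rl}x}\right),$$

with $L$ the conserved remainder. The rate units follow the axis:
Gy$^{-1}$ against dose, h$^{-1}$ against time, and mixing axes in one
computation is an error. An optional third rate $k_{sl}$ (direct S → L
linearization by simultaneous close SSBs) only adds a constant to the
supercoiled decay rate; because band data cannot distinguish the two
variants, the two-step scheme is the default and `ksl` is opt-in
(`variant = "direct_break"` in `fit_topology()`).

Assumptions worth stating: conversions are irreversible (no repair in a
cell-free tube), rates are constant over the exposure range (for long
radionuclide incubations this ignores source decay — for a nuclide with a
half-life of ~78 h the average activity over 25 h is ~90% of the initial,
so fitted per-hour rates are effective rates at the stated activity), and
every plasmid molecule sees the same exposure.

### Numerical choices

* **Removable singularity.** The closed form for $R$ is 0/0 at
  $k_{sr} = k_{rl}$. When the two decay rates agree to a relative difference
  below $10^{-8}$ the analytic limit $S_0 k_{sr} x e^{-kx}$ is used instead;
  continuity across the switch is tested to $10^{-6}$.
* **Conservation by construction.** $L$ is always computed as
  total $- S - R$, so $S + R + L$ is conserved exactly.
* **Independent oracle.** `ode_topology()` integrates the same master
  equations with `deSolve` at tight tolerances ($10^{-10}$ relative); the
  test suite requires closed-form/ODE agreement below $10^{-6}$ absolutely on
  50-point grids for all rate pairs of interest, including the singular line.
* **Fractions internally, percentages at the file boundary.** All model code
  works on $[0,1]$ fractions; gel tables and reports use 0–100 percentages.
  This avoids silent 100-fold weight errors in the fit.
* **Generalized initial state.** The textbook solution assumes
  $R(0)=L(0)=0$, but real preparations start at only 92–97% supercoiled with
  a few percent relaxed. `plasmid_init()` accepts nonzero `r0`/`l0`; the
  default reproduces the textbook scheme, and the fit estimates $S_0$ by
  default (fixable via `fit_s0 = FALSE`).

## Global weighted fitting

`fit_topology()` collapses replicate lanes to per-exposure means and sample
SDs (`summarize_replicates()`) and minimizes

$$\sum_{\text{species}} \sum_{x}
  \left(\frac{\bar y_{x,\text{species}} - \hat y_{x,\text{species}}}
             {\max(\mathrm{SD}_{x,\text{species}}, \text{floor})}\right)^2$$

jointly over the three species with bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`, rates constrained $\ge 0$, $S_0 \in [0,1]$, relative
tolerances $10^{-15}$, up to $10^4$ evaluations). Design choices:

* **Weights.** Inverse-variance weights from the replicate SDs, floored at 1
  percentage point (`sd_floor`) so single-replicate or zero-variance points
  cannot dominate; `weights = "unit"` gives an unweighted fit for data
  without replicate structure.
* **Standard errors.** Covariance $(J^\top W J)^{-1}$ rescaled by the
  reduced chi-square, the common errors-in-variance convention for nonlinear
  fits to means with empirical error bars; `scale_covariance = FALSE`
  disables the rescaling, in which case the SDs are taken at face value (the
  reported SEs then scale linearly with the SDs, while point estimates are
  invariant to a common SD rescaling either way). Whether the original
  analysis fitted $S_0$ or rescaled its covariance is not documented
  anywhere we know of, which is why both are exposed as options rather than
  hard-coded.
* **Starting values.** $S(x)$ is log-linear in $x$, so `initial_guess()`
  reads $k_{sr}$ off a log-linear regression of the supercoiled means
  (excluding zero-signal points), starts $k_{rl}$ at $k_{sr}/50$ — the
  second step is strongly rate-limiting in this assay — and $S_0$ at the
  lowest-exposure supercoiled mean. Basin-of-attraction tests confirm
  perturbed starts (×/÷3) reach the same optimum.
* **High-exposure linear band.** At high damage the linear band smears into
  fragments and its quantification degrades; `drop_linear_above` masks
  linear-band observations above a chosen exposure. The default keeps all
  points.
* **Boundaries and failure.** Parameters that converge onto the
  nonnegativity boundary are flagged in `at_boundary`; non-convergence
  produces a warning and a `converged = FALSE` flag, never a silent result.
  SEs are refused when there are no residual degrees of freedom.

## Dose–time equivalence

With the supercoiled fraction as the damage proxy, equal modelled damage
from $t$ hours of radionuclide incubation and $D$ Gy of external beam
requires $e^{-k_{sr,t}t} = e^{-k_{sr,D}D}$, hence

$$D = \frac{k_{sr,t}}{k_{sr,D}}\,t, \qquad t = \frac{k_{sr,D}}{k_{sr,t}}\,D.$$

Uncertainties are propagated to first order (delta method) through the
ratio assuming independent rate estimates:
$\mathrm{SE}(D) = D\sqrt{(\mathrm{SE}_t/k_t)^2 + (\mathrm{SE}_D/k_D)^2}$.
This choice reproduces the published worked conversions (0.48 ± 0.08 Gy and
0.11 ± 0.01 Gy per hour of incubation for ionic ⁶⁷Ga and ¹¹¹In at 0.5 MBq;
2.05 h and 9.3 ± 0.77 h per Gy in the reverse direction) to within one unit
in their last printed digit — the printed values themselves carry ~half-digit
rounding slack, e.g. 1.21/0.131 = 9.24 prints as 9.3, and the ±0.36 h
uncertainty printed for the ⁶⁷Ga time matches the delta method evaluated at
the 0.585 h⁻¹ variant of that rate rather than the 0.590 h⁻¹ used for the
point value.

For the relaxed and linear species no closed form is convenient, so
`equivalent_exposure()` inverts the fitted model numerically: a bracketing
root search matches the species proportion to $|\Delta| \le 10^{-9}$,
extending the bracket geometrically for the monotone species (S decreasing,
L nondecreasing) and requiring an explicit `branch` ("rising"/"falling") for
the unimodal R. For the supercoiled basis with a shared $S_0$ the numeric
route reproduces the ratio formula to $10^{-9}$ relative, which is tested.
Unattainable targets (e.g. any positive L when $k_{rl}=0$) raise an explicit
no-solution error.

## Densitometry

`lane_profile()` reduces a lane rectangle of a grayscale gel image to a 1-D
migration profile (per-row sums; polarity flag inverts dark-band images at
load). Band percentages are shares of the summed window integrals
(`quantify_bands()`), which errors on zero signal rather than emitting NaN
and warns when more than 10% of corrected signal lies outside all windows
(the smear regime). Windows are half-open `[start, end)` on 1-based pixel
positions; `auto_detect_windows()` splits the profile at the minima between
the three largest peaks and labels them by migration order — supercoiled
fastest, relaxed slowest, linear between, the usual order for an intact
plasmid on native agarose, and configurable because gel orientation is a
lab convention.

Baseline handling deserves a note. The obvious rolling-minimum
(morphological opening) estimator clips a slice of order
slope × band-width off every band when the background is ramped; on test
ramps this cost 4–25% of band area, well outside the 2% the synthetic
round-trip demands. The default is therefore an iterative peak-clipping
envelope (the SNIP scheme: clip each point to the mean of its two
neighbours at span $m$, for $m$ decreasing from half the window to 1),
which carves bands down to the chord of the flanking background and is
exact for linear backgrounds at any slope. A short running mean
(`smooth = 7` pixels) is applied before baseline estimation because clipping
estimators otherwise follow the lower noise envelope, leaving a positive
pedestal of order the noise amplitude under every window. Both alternative
methods remain available.

## What the generators emulate — and what they do not

`simulate_gel_dataset()` reproduces the statistical structure the fit
assumes: true proportions from the closed form at the study design points —
external beam `{0, 0.5, 1, 2, 5, 10, 20, 40}` Gy, radionuclide
`{0, 2, 4, 21, 25}` h — perturbed per lane either by per-species Gaussian
noise (default SD 5 percentage points, the mid-range of replicate scatter
seen in this assay, clipped to [0,1] and renormalized to conserve the lane
total) or by a Dirichlet draw centred on the truth (exactly mean-unbiased,
preferred near the 0/1 boundaries where clipped Gaussians are biased — the
clip bias is visible at the ~0.5 percentage-point level for species near
zero). Default replicate count is 6 per design point and the untreated
supercoiled fraction 0.97, matching typical preparations. A single integer
seed makes output byte-reproducible, and the generator restores the
caller's RNG state.

`simulate_gel_image()` renders lanes as three Gaussian bands with
integrated intensities proportional to the topology proportions, plus an
optional linear background ramp and additive Gaussian pixel noise, with a
ground-truth table for round-trip tests.

Passing tests on these generators shows the estimation and densitometry
machinery is correct *under the model's own assumptions*. Real gels add
effects the generators deliberately omit: lane-to-lane loading variation,
non-Gaussian and spatially correlated backgrounds, band skew, partial-lane
smears, saturation, and any dose dependence of the measurement error. Recovering
a rate from synthetic data therefore validates the software, not the
chemistry.

## Problem sizes and known limitations

The test suite runs stochastic-recovery studies at 200 simulated datasets
(6 replicates × 8 design points each) and checks empirical 68%-interval
coverage of the reported SEs in the band [0.55, 0.80]; ODE-oracle grids use
50 points per rate pair. These sizes give stable medians and coverage
estimates while keeping the whole suite in the tens of seconds on a single
CPU.

The published conversion rates for this assay (e.g. 1.21 ± 0.04 Gy⁻¹ and
0.017 ± 0.001 Gy⁻¹ for 1.25 ng/μL plasmid under a ¹³⁷Cs beam; 0.590 ±
0.100 h⁻¹ for 0.5 MBq ionic ⁶⁷Ga) cannot be re-derived here: the raw gel
data behind them are not publicly deposited. They ship as
`published_rates()` and function purely as simulation truths and as inputs
to the equivalence calculator. One further wrinkle is inherited from the
source: the ⁶⁷Ga 0.5 MBq supercoiled-decay rate is quoted both as 0.590 and
as 0.585 h⁻¹ in different places; `published_rates()` carries 0.590 and the
worked-example checks use each figure where it was used originally.
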