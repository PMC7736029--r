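---
title: "Models and methods behind spraydry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spraydry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spraydry)
```

`spraydry` supports early-stage, lab-scale spray-drying process
development for sugar and peptide formulations: deciding where a dryer
can be operated without product stickiness or condensation, reading
particle-formation physics out of single-droplet drying experiments,
and quantifying powder quality from thermogravimetry, laser
diffraction and micro-tomography. This vignette explains the models,
the tunable parameters and the numerical choices, and states what the
synthetic-data generators do and do not emulate.

## Moist-air bookkeeping

Every downstream calculation rests on moist-air states
(`moist_air_state()`): dry-bulb temperature $T_{db}$ (K), specific
humidity $Y$ (kg water vapor per kg dry gas), total pressure $p$ (Pa)
and the derived relative humidity. Internally everything is SI
(kelvin, pascal, kilogram, second); Celsius, percent and mL/min appear
only in the CSV readers and generators. This removes the offset bugs
that plague mixed-unit energy balances.

Saturation pressure uses a Magnus-type correlation with Buck's
coefficients,
$p_{sat}(t) = 611.21 \exp\!\big[(18.678 - t/234.5)\,t/(257.14+t)\big]$
($t$ in °C). It is accurate to well under 1% between 0 and 100 °C and
needs no tables at run time; steam tables appear only as a test
oracle. Conversions follow
$Y = 0.622\, p_v/(p - p_v)$ with $p_v = \mathrm{RH}\, p_{sat}(T)$, and
the inverse is algebraically exact, so round trips reproduce RH to
$10^{-9}$.

Two conventions worth stating:

* **Supersaturation is flagged, never clipped.** RH > 1 means
  condensation (e.g. in the cyclone), which is a process failure mode
  the models must surface, not hide.
* **Humid heat capacity uses the inlet humidity**,
  $c_{p,h} = c_{p,dry} + Y_{in} c_{p,vap}$, not a mean over the
  section. At dryer humidities (a few g/kg) the difference is far
  below sensor noise.

The evaporative temperature drop over a section where all latent heat
comes from the gas is
$\Delta T = \dot m_{evap}\, \Delta h_{vap} / (\dot m_{gas}\, c_{p,h})$ —
linear in the evaporation rate, inverse in the gas flow, and both
properties are tested exactly.

## Glass transition, sorption and the stickiness curve

Amorphous sugars plasticize with moisture. The Gordon–Taylor rule

$$T_g(w_w) = \frac{(1-w_w)\,T_{g,s} + K\,w_w\,T_{g,w}}{(1-w_w) + K\,w_w}$$

predicts the glass transition of the binary solid–water system from
the wet-basis water mass fraction $w_w$. Defaults describe the
trehalose–water pair: $T_{g,s} = 389$ K, $T_{g,w} = 136$ K,
$K = 6.04$ (published values for this pair span roughly 5.2–7.9
depending on the endpoints chosen). `fit_gordon_taylor()` estimates
$K$ by least squares with the endpoints fixed and reports a
delta-method standard error; at $n = 10$ points a $\pm 2$ SE band has
~92% nominal coverage (t distribution, 9 df), which the tests account
for.

Moisture uptake versus gas humidity uses the GAB isotherm

$$X(a_w) = \frac{X_m C k a_w}{(1-k a_w)(1-k a_w + C k a_w)}$$

on a dry basis (kg water / kg dry solid). GAB was chosen because it is
the standard sorption model for amorphous carbohydrates over the full
activity range; the shipped trehalose parameters
($X_m = 0.062$, $C = 8$, $k = 0.95$) are explicit calibration
placeholders of the right order of magnitude, meant to be refit from
user data with `fit_isotherm()` (classical quadratic-transform
initialization, then Levenberg–Marquardt). Isotherms are dry-basis
while Gordon–Taylor wants wet-basis fractions; the conversion
$w_w = X/(1+X)$ is explicit and tested.

The **stickiness curve** is the locus of gas states where the particle
surface reaches the sticky point: for each $T_{db}$ on a grid,
`build_stickiness_curve()` solves

$$T_g\big(w_w(X(\mathrm{RH}))\big) + \Delta T_{sticky} = T_{db}$$

for RH by bisection on $(10^{-6}, 0.999)$ to $10^{-8}$ — the problem
is monotone, so convergence is guaranteed — and converts the root to
specific humidity. The default offset is $\Delta T_{sticky} = 10$ K;
the sticky-point literature reports $15 \pm 5$ K, and the offset is an
ordinary argument so that band can be explored. Zone classification is
conservative: `safe` requires strictly $T_{db} < T_g$; equality falls
into `transition`; `risk` starts beyond $T_g + \Delta T_{sticky}$.
A separate strict-threshold flag (`dihydrate_risk()`, default RH >
44%) marks conditions favoring crystalline trehalose dihydrate
nucleation.

One scope decision: the psychrometric model is water-only. Runs with
ethanol co-solvent are supported by the bookkeeping (feed water
fraction below 1), but ethanol is not charted; as a plasticizer with
$T_g \approx 97$ K it would only make the stickiness constraint
tighter, so the water-only chart is the optimistic envelope and is
labelled as such.

## The dryer station model

`station_states()` propagates ambient air through the open-loop dryer:
P1 ambient, P3 heated inlet at the set temperature with ambient
humidity, P4 after atomisation, P5 column outlet, P7 collection, P9
exhaust. Assumptions, stated as model choices:

* **Evaporation is complete by P4.** Lab-scale droplets are tens of
  micrometers and dry within the nozzle region; P4 therefore takes the
  full evaporative cooling and the full humidity gain at once.
* **Wall heat loss is lumped**, one coefficient (W/K) per segment
  (column, cyclone/filter), driving the gas toward ambient. The loss
  is only measurable empirically; calibrate the coefficients from
  dry-air data where no evaporation confounds the temperatures.
* Water mass is conserved exactly across stations (tested to
  $10^{-12}$), and humidity never decreases downstream.

Supersaturation at a station flags that station but does not stop the
pipeline — a run that condenses in the cyclone is exactly the case one
wants reported in full.

The exhaust-humidity **response surface** is an ordinary least-squares
fit of RH on the full quadratic in feed rate and inlet temperature,
using only runs that passed (stable drying); failed runs are kept
aside and define the **operation limit band**: the band between the
wettest passed exhaust RH and the driest failed one. An inversion
(passed wetter than failed) is reported as an overlap warning rather
than an error.

The cyclone cut size uses the Barth equilibrium-orbit picture: the
inlet velocity $u_e = Q/(ab)$ is spun up to the inner-vortex radius by
friction-free angular-momentum conservation, $u_i = u_e r_e / r_i$
with $r_e = (D-b)/2$ and $r_i$ the vortex-finder radius; the radial
drift is $v_r = Q/(2\pi r_i h_i)$; Stokes settling in the centrifugal
field balances the drift at

$$\bar d_{50} = \sqrt{\frac{18 \mu\, v_r\, r_i}{(\rho_p-\rho_g)\,u_i^2}},$$

which scales as $Q^{-1/2}$ and $(\Delta\rho)^{-1/2}$ (tested exactly).
The geometry is fully configurable so the model can be calibrated to a
specific separator; no universal accuracy claim is made.

Yield accounting compensates the collected mass for its residual
moisture: $\mathrm{yield} = m_{prod}(1-\mathrm{RM}_{180})/(c_{feed}
V_{feed})$, invariant under unit changes and flagging values above 1
as accounting anomalies.

Sensor logs follow the standard run structure — dry air (DAP), pure
solvent (PSP), production (PrP), shut-down (S). The feed channel is
the only automatic phase discriminator (no sensor distinguishes
solvent from solution), so DAP→PSP triggers on the first sustained
non-zero feed, PrP→S on sustained feed-off, and PSP→PrP comes from an
operator mark or a supplied switch time. Steady-state extraction uses
a trailing 5-minute window with stationarity thresholds sd(RH) < 1 %RH
and sd(T) < 1 K; the filter-fouling check compares exhaust pressure
against an initial baseline with a 5% relative threshold.

## Single-droplet drying analysis

Acoustically levitated droplets flatten into oblate spheroids; the
image pipeline delivers per-frame binary masks or the axes of the
moment-equivalent ellipse (`ellipse_from_moments()`, which matches the
mask's second-order central moments; a $+1/12$ term accounts for the
pixel's own second moment). The axis convention is equatorial = image
major axis, polar = minor axis. Surface and volume use the closed
oblate formulas, with a series branch for the area near $a = b$ so the
sphere limit is exact rather than 0/0.

The d²-law regression variable is the squared **volume-equivalent
diameter** $d_{eq} = (6V/\pi)^{1/3}$ — the standard convention when
the instrument reports surface and volume rather than a single
diameter. `fit_evaporation_rate()` estimates $\kappa$ as minus the OLS
slope of $d_{eq}^2(t)$ over a pre-lock window (default: the first 30%
of the record).

The **lock point** — skin formation, shrinkage stop — is the earliest
time from which the local $|d^2|$ slope stays below
`slope_fraction * kappa` (default 0.1) for at least `persistence`
samples (default 5). Both thresholds are ordinary arguments; the
defaults suppress single-frame noise without delaying detection by
more than one sample on clean plateaus.

Particle-formation physics enters through the Péclet number
$Pe = \kappa/(8 D_s)$ and the steady-state surface enrichment

$$E = c_s/c_m \approx 1 + Pe/5 + Pe^2/100 + Pe^3/4000,$$

valid for $Pe < 20$; larger values warn rather than error because
practically relevant estimates sit just under that bound. The cubic is
strictly increasing, so `invert_enrichment()` bisects to $10^{-10}$
and the round trip is exact to $10^{-8}$. `estimate_diffusivity()`
chains these: with the tomography-derived solid density as the surface
concentration at the lock point, $E = c_s/c_m$, $Pe$ from inversion,
$D_s = \kappa/(8Pe)$; a flat profile ($c_s = c_m$) is a flagged
degenerate result, not an error. Optional standard errors on $\kappa$
and $c_s$ propagate to $Pe$ and $D_s$ by the first-order delta method.

## Voxel morphology descriptors

From a segmented 3D particle the package computes, in one consistent
voxel-counting convention: the solid volume $V_V$, the
region-of-interest volume $V_{ROI,V}$ (solid plus enclosed pores, via
`fill_roi()`), the ROI surface area $V_{ROI,A}$, the convex-hull
volume $V_{CH,V}$, and

$$\psi = \frac{\pi^{1/3} (6 V_{ROI,V})^{2/3}}{V_{ROI,A}}, \quad
S_{V_{ROI}} = \frac{V_V}{V_{ROI,V}}, \quad
S_{V_{CH}} = \frac{V_{ROI,V}}{V_{CH,V}}, \quad
\rho_{XRT} = \frac{m_{SDD}}{V_V}.$$

Numerical choices:

* **Surface area** is the total variation of a Gaussian-smoothed
  ($\sigma = 1.2$ voxels) indicator function, computed by FFT. Naive
  voxel-face counting overestimates a sphere's area by ~50% and would
  wreck $\psi$; the smoothed-gradient estimator is within a fraction
  of a percent on digitized balls of radius 20–40 voxels, comfortably
  inside the 3% discretization band the tests assert.
* **Convex hull** facets come from a quickhull over the ROI
  surface-voxel centers (validated against a brute-force
  facet-enumeration oracle), but the hull *volume* used in the
  convexity is the count of voxel centers inside the hull polytope —
  the same counting convention as $V_{ROI,V}$ — so $S_{V_{CH}} \le 1$
  holds by construction and a digitized ball scores exactly 1.
* **Connectivity** uses the standard complementary pair:
  6-neighbourhood for solid/ROI, 26 for the background flood fill that
  identifies enclosed cavities, avoiding tunnel paradoxes. Cavities
  open to the outside (cups) are deliberately not filled.

`generate_particle()` provides the reference shapes: dense spheres,
hollow shells with a stated cavity volume fraction, and buckled
particles built as spheres with a seeded low-order spherical-harmonic
radial perturbation. The harmonic field is normalized to its 90th
absolute percentile and clipped, so the stated amplitude is realized
over most of the surface instead of at a single lobe; amplitude 0
reduces exactly to the sphere.

## The dip test

Laser-diffraction PSDs of agglomerated powders are multimodal; the
package scores this with Hartigan's dip statistic — the smallest
sup-norm distance between the empirical CDF and any unimodal CDF.
The implementation conditions on the mode: a unimodal CDF is convex
left of its mode and concave right of it (an atom at the mode is
allowed), so the two sides decouple. For a candidate mode, a convex
branch rising from zero fits inside the $d$-tube around the ECDF iff
the lower convex hull of the tube's upper corners dominates the lower
corners at every data point; because the whole tube shifts linearly
with $d$, the minimal feasible $d$ per side is available in closed
form as half the largest hull deficit. The left-side minimum is
nondecreasing and the right-side one nonincreasing in the mode
position, so the best mode sits at their crossing (binary search for
large samples, exhaustive scan below 65 distinct values). The rare
regime where the $G \le 1$ cap binds falls back to bisection with
capped bounds. The tests validate this construction to $10^{-9}$
against an independent oracle that decides tube feasibility by
quadratic programming, across seeded batteries including ties and
bimodal samples, and pin the canonical values (any two-point sample
dips at exactly 1/4).

`unimodality_probability()` calibrates the dip against uniform null
samples of the same size — the canonical dip-test null — with a
seeded, caller-RNG-preserving bootstrap (default 2000 replicates).
The reported probability is the fraction of null dips at least as
large as the observed one; under the null it is uniform by
construction, so calibration is checked as a type-I error rate
(empirically within [0.03, 0.07] at the nominal 5% over 1000 uniform
replicates at $n = 100$). Because the dip needs a sample rather than
a histogram, `psd_resample()` draws sizes volume-weighted with
uniform jitter in log-size within bins (default $n = 500$), and
`deagglomeration_report()` applies the test to the log-sizes of the
no-ultrasound (LD0) and post-ultrasound (LD2) stages.

## Thermogravimetric moisture accounting

`residual_moisture_at()` reads cumulative mass loss from the start of
the run (linear interpolation in temperature) at 80, 110 and 180 °C:
unbound water, water released around the dihydrate dehydration
(~97 °C), and entrapped moisture released above the glass transition.
The 80–110 °C step bounds the crystalline dihydrate content through
the hydrate-water stoichiometry $2 M_{water}/M_{dihydrate} \approx
0.0952$ (18.015 and 378.33 g/mol). Vacuum-drying removal fractions
compare gravimetric loss against the TGA-unbound moisture and may
legitimately exceed 100% (kinetically hindered desorption during TGA);
such values are flagged, not rejected.
`reference_moisture_table()` ships the published TG-MS and
vacuum-drying results of the trehalose (SPT1–SPT6) and glucagon
(SPG1–SPG5) reference campaigns that the worked examples and the
acceptance script recompute from.

## What the synthetic data do and do not emulate

The generators are seeded (one top-level seed fans out through fixed
per-generator counters, so adding a generator never perturbs existing
fixtures) and deterministic, and every output passes the consuming
module's validation unchanged. They emulate: d²-law shrinkage with a
lock point and multiplicative optical noise; four-phase sensor logs
with first-order lag transitions and additive channel noise;
multi-step sigmoidal TGA curves; lognormal-mixture volume-weighted
PSDs; GAB sorption data.

They deliberately do not emulate: internal concentration fields or
droplet oscillation (no rigorous droplet simulation), instrument
drift, spray-plume polydispersity, real segmentation artifacts in
tomography masks, or mixed-solvent evaporation. Passing tests
therefore demonstrate correct *recovery of the model's own structure*
under realistic noise magnitudes — parameter identifiability, solver
correctness, calibration of the statistics — not validation against
instruments.

## Problem sizes and reproducibility

The test suite and acceptance script run at desk scale by choice:
digitized balls of radius 20–40 voxels (where the analytic bands are
already tight), droplet series of a few hundred frames, 200-replicate
fitting batteries, and a dip-test calibration of 1000 uniform
replicates at $n = 100$ against a 2000-replicate null. All stochastic
results are reproducible bit for bit from the seeds recorded in the
tests and the acceptance script's `--seed` argument.

## Known limitations

* The psychrometric chart is water-only; ethanol effects are tracked
  in mass balances but not charted.
* The shipped GAB parameters are placeholders pending a user refit.
* The cyclone model is a calibratable idealization; it ignores wall
  friction and vortex-core structure.
* Heat losses are lumped per segment, not resolved along the column.
* Zone classification uses equilibrium moisture at the local gas
  state; finite sorption kinetics make it conservative for short
  residence times.
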