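---
title: "Methods: pulsed transient-plane-source monitoring of cell layers"
author: "thermopulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulsed transient-plane-source monitoring of cell layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement principle

A planar resistive meander on a thin polyimide foil sits at the bottom of a
liquid culture reservoir. Square constant-current pulses Joule-heat the
structure; because the metal's resistance is an almost perfectly linear
thermometer,

$$R(T) = R_\mathrm{ref}\,[1 + \alpha\,(T - T_\mathrm{ref})],$$

the 4-wire voltage read back during the pulse encodes the heater's own
temperature transient. How fast the heater warms is set by the thermal
properties of whatever it touches: a semi-infinite medium of effusivity
$e = \sqrt{k\rho c_p}$ under constant areal flux $q$ warms the interface as

$$\Delta T(t) = \frac{2q}{e}\sqrt{\frac{t}{\pi}},$$

linear in $\sqrt{t}$ with slope $2q/(e\sqrt{\pi})$. (The units of $e$,
$\mathrm{W\,s^{1/2}\,m^{-2}\,K^{-1}}$, force the square root in its
definition.) Yeast cells conduct heat worse than the aqueous medium they
grow in, so cells that settle or proliferate on the sensor form a thermally
insulating blanket: the early transient steepens as the layer grows.

The read-out statistic is deliberately simple: an ordinary least-squares
slope of the transient against $\sqrt{t}$ inside a fixed early window
(0.16--0.56 $\sqrt{\mathrm{s}}$, i.e. 25.6--313.6 ms), repeated every
pulse, and expressed as the percent change relative to the first pulse,

$$\mathrm{pct}_i = 100\,\frac{s_i - s_0}{s_0}.$$

Normalizing each sensor to its own first pulse cancels the unit-to-unit
spread in cold resistance (7--10 $\Omega$), so different sensors are
directly comparable. The window starts once the pulse has traversed the
40 µm substrate (probing depth $2\sqrt{at}$ reaches 40 µm in polyimide
after ~5 ms) and ends long before the far field matters.

## The forward simulator

`simulate_step_response()` solves one-dimensional transient conduction
through the layered stack around the heater, which is treated as a lumped
node of areal heat capacity 51.7 J m$^{-2}$ K$^{-1}$ (15 µm of copper)
receiving the full electrical power; the solver itself resolves how the
heat splits between the substrate and the culture. The meander is modelled
as a uniform 9 mm × 9 mm planar source: the pulse penetrates well under a
millimetre in one second, far less than the lateral extent, so lateral
losses are neglected. The backside (the backplate cut-out that exists
precisely to block heat loss) is polyimide backed by an adiabatic plane;
a semi-infinite backing is available as configuration.

Numerics: control volumes with steps of at most 1 µm inside thin films and
a geometrically stretched grid (first cell 2 µm, ratio 1.2) truncated at
5 mm with a zero-flux far boundary — about seven times the one-second
penetration depth in water, and the solver refuses configurations where
the truncation comes within twice the penetration. Time stepping is
backward Euler (L-stable, so micron-thin cells never oscillate, and exactly
energy-conserving with these boundaries; the stored-versus-injected energy
mismatch is checked to round-off on every run). Four implicit substeps per
500 Hz output sample suffice except at onset, where the first sample
interval uses 32 geometrically graded substeps to resolve the $\sqrt{t}$
singularity. Against the closed-form half-space solution the solver's
window slope agrees to 0.3%, and halving all steps moves it by < 0.03%.

Constant nominal power is the default drive; optional electro-thermal
coupling (fixed current, power rising with resistance, an effect of order
$\alpha\Delta T \approx$ 2--4%) is available via `couple_alpha`.

## The synthetic cultures

No measured datasets accompany the method, so the package generates its
own study conditions end-to-end:

* **Sedimentation** — a two-fold dilution series (8 down to 0.125 mg/mL,
  plus a water blank) of non-growing cells settling by Stokes drag
  ($v_s = \tfrac{2}{9}\Delta\rho\,g\,r^2/\mu \approx 1.36$ µm/s for
  $r = 2.5$ µm, $\Delta\rho = 100$ kg m$^{-3}$). A 1.5 mL fill of the
  19 mm reservoir gives a 5.3 mm column, so the deposit plateaus at
  $H/v_s \approx 1.1$ h, inside the observed first 1.5 h. The final
  areal deposit follows from mass balance (concentration × column height
  / cell density).
* **Proliferation** — lag of 5 h, then logistic growth with rate
  $\ln 2 / T_d$ ($T_d$ = 90 min by default) toward a carrying capacity
  set by the fermentable glucose, $K = \mathrm{OD}_0 + Y\,G$ with
  $Y = 0.5$ OD per g/L. OD600 maps to settled areal biovolume through a
  single constant, $1.2\times10^{-5}$ m$^3$ m$^{-2}$ per OD unit: the
  full-settling mass balance of the 10 mL column gives
  $\approx 2.3\times10^{-5}$ (an OD unit is roughly $6.5\times10^{-4}$
  volume fraction), halved for incomplete settling during growth. It is
  an effective constant, not a claim; only ratios and orderings carry
  meaning.

The settled layer is rendered as an effective medium: thickness
= areal biovolume / packing fraction (0.64, random close packing), with
Maxwell–Eucken mixing (medium continuous) for the conductivity — series
and parallel mixing are exposed as sensitivity bounds. Cell thermal
properties default to $k = 0.45$ W m$^{-1}$ K$^{-1}$, $\rho = 1100$
kg m$^{-3}$, $c_p = 3500$ J kg$^{-1}$ K$^{-1}$ — configuration values
inside literature-plausible ranges; the only load-bearing assumption is
that cell conductivity is below the medium's.

Raw records add white Gaussian voltage noise, default 0.2 mV — the
simplest model that keeps the in-window regressions at realistic quality
($R^2 \approx 0.996$ at the standard drive, comfortably above the 0.98
floor the method requires); optional ADC quantization is available. All
randomness flows from one top-level seed through named substreams, so a
configuration plus seed reproduces a dataset byte for byte.

A separate *calibration-mode* generator bypasses the physics entirely and
draws endpoint percent changes straight from the linear response line
(slope 0.7806% per mg/mL, intercept −0.2194%) plus noise. It exists
because the physics-based endpoint magnitude depends on the assumed cell
properties, while calibration fitting and inverse prediction deserve a
ground truth that is linear by construction. The line is interpreted with
concentration on a linear abscissa; reading it against
$\log_{10}$-concentration would imply negative responses over most of the
tested range.

## Analysis choices

Window membership is a closed interval on sample timestamps: at 500 Hz
(samples at 2, 4, ... ms) the default window holds 144 samples. Slopes may
be regressed on the voltage or on the converted temperature curve; the two
are affine images of each other, so percent-change series agree to
machine precision (property-tested), and the temperature domain is the
default only because its slope units (K s$^{-1/2}$) are physically
interpretable. The baseline is strictly the first pulse; a mean-of-first-k
baseline is available for noise robustness but off by default. Degenerate
pulses (non-finite samples) are dropped with a warning. Endpoint
statistics default to the 2--12 h window, after sedimentation has
plateaued.

## Quantification

**Calibration.** Endpoint percent change against concentration is fitted
by ordinary least squares; inverse prediction is
$\hat c = (y - b)/a$ with a delta-method uncertainty
$\sigma_\mathrm{res}/|a|$, a convention chosen because no more specific
procedure for the reported prediction uncertainty is available.

**Growth.** The percent-change series of a proliferation run is fitted
with a lag-floored logistic — flat at the inoculum level until the lag
ends, logistic afterwards — rather than a plain 4-parameter logistic: on
the generator's own trajectory family the plain logistic's left tail
cannot stay flat and overestimates the rate by ~8% even without noise.
Doubling time is $60\ln 2/\hat r$ minutes.

Two refinements matter for accuracy:

1. *Sensor linearization.* The window slope's response to a thin film is
   convex in thickness: a film of thickness $d$ has internal diffusion
   time $d^2/a$, so very thin films shift mostly the intercept of the
   transient, and the slope response only becomes affine once the film
   occupies a noticeable part of the window's probing depth (roughly
   40--110 µm here, where it is affine within 5%). Treating percent
   change as proportional to biomass therefore inflates the apparent
   growth rate by ~13% under the default conditions.
   `slope_response()` tabulates the package's own slope-versus-thickness
   curve with the solver, and `fit_growth(..., response = )` fits the
   logistic *composed* with that curve, which removes the bias (noise-free
   recovery is exact to 0.01%).
2. *Correlated baseline noise.* Every percent-change value shares the
   first pulse's noise draw as a common additive shift (~0.45 percentage
   points at default noise). The composed fit carries a free offset to
   absorb it; omitting the offset roughly doubles the rate uncertainty
   and skews it. When the inoculum layer thickness is known — it is
   experiment metadata, set by the starting OD — the logistic can
   additionally be anchored through it (`th0 =`), removing the midpoint
   as a free parameter.

Phase segmentation is heuristic by design: lag ends at the first
persistent excursion above baseline + 3 × baseline noise; stationary
phase starts at the plateau time (first time from which the series stays
within tolerance of its trailing-quarter mean); absent phases are
flagged, not errors.

## Problem sizes

The shipped tests and the acceptance script run experiments at the sizes
the package recommends for synthetic studies: sedimentation runs of
1.5--2.2 h (90--130 pulses at the 61 s cadence) rather than the full 12 h
protocol, and 18 h proliferation runs (216 pulses at the 301 s cadence),
with five replicate runs behind the reported doubling time, whose
single-run estimate scatters by ~8%.

## Known limitations

* The convex thin-film response means the *plain* proportionality-based
  growth fit underestimates the doubling time by ~10--15% under default
  conditions; use the response-composed fit when quantitative kinetics
  matter. Relatedly, the linear endpoint-versus-concentration response is
  reproduced by the physics only above roughly 20 µm equivalent layer
  thickness; the real sensor's measured linearity down to sub-monolayer
  coverage involves discrete-cell effects a 1-D effective layer cannot
  capture.
* At the default noise level the endpoint separations of the lowest
  dilution steps (≲ 0.05 percentage points) sit below the first-pulse
  normalization noise, so orderings at the bottom of the series are only
  meaningful for the deterministic response or after heavy replication —
  consistent with the ~0.29 mg/mL inverse-prediction uncertainty of the
  calibration itself.
* The thermal model is one-dimensional and conduction-only: no meander
  geometry, no convection in the liquid, no evaporation, and no metabolic
  heat; the cooling intervals are assumed to restore ambient temperature
  exactly. Biology is likewise deliberately minimal (no nutrient
  diffusion, cell-size distributions or biofilm matrix).
* Passing tests on these synthetic cultures demonstrates the pipeline's
  internal consistency and sensitivity directions, not the behaviour of
  real cultures.
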