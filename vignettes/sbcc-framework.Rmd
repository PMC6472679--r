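---
title: "Evaluating lobster rearing conditions in sea-based containers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating lobster rearing conditions in sea-based containers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbcc)
```

## The problem

Sea Based Container Culture (SBCC) rears European lobsters (*Homarus
gammarus*) in porous containers moored at sea, relying on the ambient flow to
deliver oxygenated water and remove waste. Whether a site and a vertical
position in the water column are suitable depends on the flow *inside* the
container, which cannot easily be measured but can be predicted from the
external conditions. `sbcc` implements that prediction chain and scores the
result against the lobster's physiological and behavioural limits:

1. characterise the **External Velocity Profile (EVP)** — tidal currents,
   wave orbital velocities and turbulent fluctuations as functions of height
   above the seabed — plus the dissolved-oxygen (DO) climate;
2. map the EVP to the **Internal Velocity Profile (IVP)** through linear
   transfer functions fitted for a specific container design, with modifiers
   for biofouling coverage;
3. convert the DO requirement into a minimum through-flow velocity from a
   supply/consumption budget;
4. report, per height bin and per biofouling scenario, the **percentage of
   time** and the **longest continuous period** for which the IVP violates
   each limit.

The limits are: foraging improves below 0.1 m/s (`u_forage`), mobility and
olfaction are severely impaired above 0.27 m/s (`u_mobility`), and the DO
velocity limit `u_DO` derived below. DO concentration thresholds are
4.5 mg/L for survival and 6.4 mg/L for optimal growth.

## Wave kinematics

For a sea state of height $H$ and period $T$ the wavelength is solved
iteratively from

$$\lambda = \frac{gT^2}{2\pi}\tanh\frac{2\pi H}{\lambda},$$

by damped fixed-point iteration seeded at the deep-water wavelength
$gT^2/2\pi$ (tolerance $10^{-4}$ m, at most 200 iterations; each step
averages the current iterate with its image, which converges for every sea
state we generate). Note the wave height appears inside the hyperbolic
tangent: this is the form the framework adopts, and it yields the
case-study wavelength of 44.0 m for the H = 3.99 m, T = 7.4 s storm state.
The classical linear-theory relation has the water *depth* there instead;
since the two disagree in general, both are provided
(`formula = "printed"` / `"standard"` in `solve_dispersion()`), with the
first as the default because it is the form whose case-study output is
reproducible. The wave number is taken as $k = 2\pi/\lambda$ throughout —
the only form dimensionally consistent with the exponential depth decay.

A state is *deep water* when $d > \lambda/2$ (strict). Deep-water orbital
velocities are circular,

$$u = \frac{\pi H}{T}e^{kz}\cos\theta,\qquad w = \frac{\pi H}{T}e^{kz}\sin\theta,$$

with $z \le 0$ measured down from the surface. Only the deep-water case is
implemented; intermediate/shallow elliptic kinematics are out of scope, and
`orbital_velocity()` refuses a `not_deep` state rather than extrapolate.
Profiles are evaluated at phase $\theta = 0$, the amplitude envelope, because
the framework compares peak magnitudes against limits. Heights above the
seabed (the ADCP convention, used everywhere else in the package) are
converted to $z$ at a single site, `height_to_z()`.

## Turbulence

Instantaneous velocity is decomposed as $u = \bar u + u'$ over fixed
averaging windows (default 600 s, matching the 10-minute mean convention of
ADCP processing; a partial trailing window is dropped, and plain mean
removal is used — no within-window detrending). Turbulence intensity is
$I = u'_{RMS}/\bar u$. The framework's default bulk intensity is the
depth-averaged maximum observed at the case-study sites, $I = 0.8$; a
per-depth profile can be supplied instead via the coefficients.

## Transfer functions

For a container design characterised in flume experiments, internal
velocity is linear in external velocity with intercept zero. The peak
instantaneous internal velocity is

$$u_{in} = u_{ex}\,m_{cur}(1 + n_{cur}\,Bio) +
           u_{ex}\,I\,m_{turb}(1 + n_{turb}\,Bio),$$

where $Bio \in [0,1]$ is the biofouling coverage fraction. Defaults (design
"SBCC 1" at 90° angle of attack): $m_{cur} = 0.2411$, $m_{turb} = 0.8855$,
$n_{cur} = -0.4762$, $n_{turb} = 0.1243$, $I = 0.8$. So a clean container
passes ~24% of the mean current and ~89% of the turbulent fluctuation;
fouling suppresses the current (−31% at 66% coverage) while enhancing
internal turbulence (+4%/+8% at 33%/66%). With the defaults the turbulence
term is $I\,m_{turb}/m_{cur} \approx 2.9$ times the current term, which is
why the mobility limit is evaluated both with and without it. Coverage is
stored as a fraction; configuration and command line also accept
percentages. Coverage large enough to drive $1 + n_{cur}Bio$ negative is
outside the linear model's validity and is an error, not a clamp.

Wave orbital amplitudes, when included, are transferred with the current
coefficients — the flume characterisation provides no wave-specific
coefficients, and the source framework treats "current and wave" as one
magnitude.

## The DO velocity limit

A stocked container of volume $V$ (L) holding a lobster consuming oxygen at
$C$ (mg/s) has, with no through-flow, an oxygen headroom time constant

$$t = \frac{V\,(DO_{sea} - DO_{lobster})}{C},$$

and an array of containers of along-flow length $L$ needs through-flow of at
least $u_{DO} = L/t$ to be flushed within that time. Units are enforced at
the boundary (mg/L, L, mg/s) so no hidden conversion exists. Case-study
values: $DO_{sea} = 8.98$ mg/L (annual minimum), $DO_{lobster} = 6.4$ mg/L,
$C = 5\times10^{-5}$ mg/s (150 g lobster), $L = 97.6$ m, giving
$t \approx 15.9$ h and $u_{DO} \approx 1.70$ mm/s:

```{r}
do_budget()
```

The container volume is not a documented measurement of the case-study
system; the shipped default $V = 1.109$ L is back-derived from its 15.9 h
time constant and
must be replaced with the real volume in any new application. `u_DO` is
always recomputed from the configuration, never hard-coded.

## Exceedance statistics

Limits are compared with strict inequalities ("less than" / "greater
than"); ties count as non-exceeding, a measure-zero choice on continuous
data. Percentage of time uses valid (non-missing) samples as the
denominator. The longest continuous period is the longest run of
consecutive qualifying samples times the nominal cadence; a missing sample,
or a time gap longer than `gap_factor` × cadence (default 1.5), terminates a
run, so instrument deployment gaps are never counted as continuous
exposure. Field records rarely document their gap handling; this policy is
our explicit choice and is configurable. The DO condition is evaluated on
the current-only IVP (oxygen supply is driven by mean flow); the mobility
condition is reported both without and with the turbulence term.

## What the synthetic generator emulates

No field campaign data ship with the package; `gen_current_field()`
produces an EVP with the statistical character of the Falmouth-bay case
study:

* **vertical shear**: long-run mean speed interpolating linearly from
  0.11 m/s at the seabed to 0.24 m/s at the surface over a 30 m column;
* **tidal structure**: a semidiurnal M2 constituent (12.42 h) beating
  against S2 (12.00 h, relative amplitude 0.3), producing the half-monthly
  spring–neap envelope (~14.77 d);
* **sample noise**: multiplicative Gaussian noise, sd 0.15, chosen once so
  that per-height maxima of a multi-month run fall near the observed
  0.35–0.69 m/s band while leaving long-run means unbiased (the rectified
  tidal modulation is normalised by its realised mean, so per-height means
  equal the configured shear by construction);
* **turbulence**: `gen_turbulent_series()` superimposes Gaussian
  fluctuations with RMS equal to intensity × local mean (default 0.8);
* **DO climate**: a sinusoidal annual cycle with configurable minimum
  (default 8.98 mg/L, the observed annual minimum) and maximum
  (default 10.5 mg/L, a realistic temperate-shelf summer-winter span,
  chosen once), minimum in late August.

What it does **not** emulate: directional currents (the framework consumes
speed magnitude only), the wind-driven mid-column velocity dip seen in
measured mean profiles, storm-surge extremes beyond the Gaussian tail,
spatially varying DO, or any covariance between waves, DO and currents.
Passing tests on this generator therefore demonstrate that the machinery is
correct and that qualitative depth/coverage orderings hold, not that the
published site-specific exceedance percentages are reproduced — those derive
from a proprietary field record. Default record length is 330 days at
600 s cadence with 2 m height bins, long enough for the spring–neap cycle
to average out; tests use shorter spans (days to a month) where only
structural properties are asserted.

## Degenerate inputs and numerical choices

* Missing samples are explicit `NA`s from file ingest onward; they
  propagate through the transfer and are excluded from denominators.
* Duplicate or non-monotone timestamps are hard errors naming the
  timestamp — silent reordering of instrument records hides real faults.
* Zero tidal amplitude degenerates to the bare shear profile; zero noise
  is exactly deterministic; an all-missing series refuses to produce a
  percentage rather than return `NaN`.
* The generator refuses a cadence coarser than a quarter of the fastest
  constituent period (aliasing).
* All randomness is routed through a single integer seed per generator
  call; reruns are bit-identical.

## Limitations

Behavioural limits come from experiments on adult lobsters in a flume whose
turbulence was not characterised; the DO budget assumes a single
maximum-size lobster, no biofouling respiration and no temperature or
salinity dependence of oxygen saturation; food availability is not
modelled. The transfer coefficients are taken as given for one container
design — re-deriving them from flume data is out of scope. These mirror the
stated limitations of the framework the package implements.
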