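---
title: "Detecting and modelling twilight ascents from multi-sensor geolocator tags"
author: "swiftascent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and modelling twilight ascents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(swiftascent)
```

## The problem

Small aerial insectivores such as swifts regularly climb several hundred
metres around dawn and dusk and return to their cruising altitude within the
hour. Multi-sensor geolocator tags make this behaviour quantifiable over a
full annual cycle: they record light and vertical-axis activity every 5
minutes and air pressure and temperature every 30 minutes. `swiftascent`
implements the complete analysis chain from those raw channels to a
statistical test of what drives the ascents — plus a synthetic annual-cycle
generator with full ground truth, so every stage is testable without field
data.

The chain is:

1. **Twilight annotation** (`detect_twilights`, `flag_unnatural`): threshold
   crossings of the light curve give dawn and dusk per civil day; abrupt
   light steps (a bird entering or leaving a dark nest cavity) mark an event
   as unnatural.
2. **Geolocation** (`estimate_positions`): a grid hidden Markov model turns
   the twilight times into a probability map per event; `sample_tracks`
   bootstraps tracks from those maps, `median_track` gives point estimates.
3. **Altimetry** (`pressure_to_altitude`, `ascent_height`): the
   international barometric formula converts tag pressure to altitude ASL
   against the sea-level pressure at the bird's estimated position; the
   twilight-ascent statistic compares the altitude at the twilight with the
   12-h baseline around it.
4. **Phases and weather** (`phase_of_position`, `annotate_weather`): each
   twilight is assigned to breeding / migration / non-breeding by a spatial
   rule and annotated with gridded weather and 24-h change factors.
5. **Inference** (`fit_ascent_model`, `run_ensemble`,
   `wilcoxon_median_ascent`, `activity_altitude_slope`): an
   AR(1)-correlated binomial mixed model for the binary ascent response,
   refitted over an ensemble of redrawn tracks with a strict
   all-confidence-intervals relevance rule.

## The core model

The response is binary: did the bird climb at least 300 m at this twilight?
The height of a twilight ascent is

> (mean of the two pressure-derived altitudes nearest the event) −
> (mean altitude over 6 h before and 6 h after, the twilight hour excluded).

Altitude comes from the barometric formula
$h = \frac{T_0}{dT/dh}\left(1 - (p_h/p_0)^{(\kappa-1)/\kappa}\right)$
with $T_0 = 288.15$ K, $dT/dh = 0.0065$ K/m, $\kappa = 1.235$. Because
light-level positions are approximate, $h$ is above sea level, never above
ground.

The regression is a binomial (logit) mixed model fitted by penalized
quasi-likelihood (`MASS::glmmPQL`), with

* fixed factors: annual-cycle phase (reference `migration`), twilight type
  (reference `dawn`), mean 12-h flight altitude, the four weather state
  variables (MSLP, 2-m temperature, relative humidity, wind speed at
  1000 mbar), and six absolute 24-h change factors (pressure, temperature,
  humidity; before and after the event). All continuous factors are
  z-transformed so effect sizes are comparable;
* a random intercept for individual nested in population;
* an AR(1) correlation (`nlme::corAR1`) over the twilight sequence within
  individual — dawn→dusk and dusk→dawn are both lag 1, because the response
  is defined per twilight, not per day.

Positions are uncertain, so phase membership is probabilistic. The ensemble
(`run_ensemble`) redraws one bootstrap track per individual per run,
rebuilds phase labels and weather annotations, and refits. Confidence
intervals are estimate ± 2 standard errors, and a factor counts as
*statistically relevant only when zero is outside the interval in every
run* — a single run crossing zero removes the flag. Non-converged runs are
excluded; more than 20 % of them aborts the ensemble.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| light threshold | half the sensor ceiling | sensor units | calibrated so the crossing corresponds to solar elevation 0° |
| unnatural-step fraction | 0.8 | of dynamic range | a quantitative stand-in for "abrupt": one 5-min step ≥ 80 % of the range is not the sun |
| ascent threshold | 300 (100 supported) | m | roughly half of observed ascents reach it; conclusions are insensitive to 100 m |
| baseline window | 6 h + 6 h, 1 h excluded | — | the 12-h day-scale context of the event; the excluded hour contains the ascent itself |
| positional grid | 1° cells | degrees | coarser than twilight-time information, finer than the 2.5° weather grid |
| movement prior sd | 1 | °/twilight | a random-walk scale consistent with observed between-twilight displacements |
| twilight error sd | 8 | min | threshold-method twilight scatter under moderate shading |
| bootstrap tracks | 10,000 | — | phase-frequency resolution of ~1 % |
| model runs | 100 | — | the all-CIs rule needs enough runs to be strict |

## What the generator emulates — and what it does not

`simulate_annual_cycle` produces one tag deployment with truth: a colony
tail, an autumn great-circle migration to a tropical residence site, a
spring return; light as a logistic function of solar elevation (threshold
crossed at elevation 0°) with optional cavity truncation during breeding
(per-twilight Bernoulli, default 0.9, producing the characteristic abrupt
unnatural events); pressure encoding true altitude through the inverse
barometric formula against a synthetic synoptic field; activity drawn from
flapping / gliding / resting regimes.

Altitude has four components: per-phase cruising levels (migration travel
legs are multi-day continuous flapping at 2000–3000 m, matching sustained
migratory flight), a within-day AR(1) wander (`alt_wander_sd`), a
day-to-day cruising offset (`day_alt_sd`), and a mild diurnal cycle at the
residence site (`nb_diurnal_amp`). Twilight offsets are drawn per event:
with the phase- and type-specific ascent probability the bird climbs by
`ascent_mean ± ascent_sd` for the half hour around the twilight; otherwise
it shifts by a small `nonascent_mean ± nonascent_sd`. Defaults
(`ascent_mean` 400 m, non-ascent offset +120 m at the residence site, dawn
probability 0.5 there with dusk odds halved) were chosen once so that the
default cohort reproduces the qualitative pattern of the field system —
non-breeding ascent frequency about twice migration's, dawn about twice
dusk, a median all-twilight height difference of a few hundred metres —
without claiming any real dataset's numbers.

The weather field is a base MSLP plus travelling Gaussian front anomalies
with correlated temperature, humidity and wind signatures, each variable
carrying its own harmonic texture so that no two fields are collinear. The
generator does **not** emulate: land/sea masks, terrain (altitudes are ASL
only), realistic atmospheric physics, sensor drift or battery failure,
foraging decisions, or any behavioural response to weather. Passing tests
therefore show the pipeline recovers what this generator encodes — they do
not validate the behavioural model of a real swift.

## Numerical choices

* **Threshold crossings** are interpolated linearly between the bracketing
  5-min samples; a sample exactly on the threshold starts the crossing
  interval. Per civil day the main daylight block is the longest
  above-threshold run, so dawn is the last upward crossing of the morning.
* **Unnatural boundary** is inclusive: a step of exactly the configured
  fraction flags the event.
* **Twilight likelihood**: instead of root-finding a predicted twilight
  time per grid cell, the solar elevation at the observed time is divided
  by the local elevation rate (floored at 0.02°/min near the poles) to give
  a time residual; a Gaussian error model and a direction check (rising sun
  for dawn) complete the per-cell likelihood. The random-walk kernel is
  kept symmetric (no row normalisation) so one operator serves the forward
  and backward passes; per-step renormalisation absorbs edge truncation.
* **Two-closest-samples rule**: one sample either side of the event when
  both exist within ±90 min, else the two nearest overall; fewer than two
  is a missing-data signal, as is baseline coverage below 50 %.
* **Ascent boundary** is inclusive (`height ≥ threshold`).
* **Baseline window**: the field description of "the 11 closest hours"
  conflicts with the explicit "6 h before and 6 h after, excluding the
  twilight hour" (12 h); the 6+6 arithmetic is implemented and the window
  is configurable.
* **Weather windows**: an event exactly on a 6-h boundary belongs to the
  window starting there; spatial lookup is nearest cell (2.5° cells dwarf
  positional precision); change factors enter the model as absolute values
  (stable vs changing weather, sign disregarded) with signed copies kept.
* **Phase boundaries** are inclusive on the migration side (exactly 200 km,
  exactly 15° N), and the colony-distance rule is applied first.
* **Wilcoxon test**: zeros dropped, average ranks on ties; exact p up to
  n = 25 (convolution over doubled ranks when ties are present), normal
  approximation with tie correction above.
* **PQL fallback**: with very few populations the nested variance is on the
  boundary and the inner lme can abort with a singular system; the fitter
  retries with the individual-level intercept (AR(1) kept) and records
  which grouping was used.

## Problem sizes used by the test suite

The full study conditions (tens of birds over a year, 10,000 tracks, 100
model runs) are the package defaults. The test suite exercises the same
code at desk scale, chosen once: parameter-recovery runs use 10 replicate
cohorts (8 birds for the effect-recovery arm, 4 for the type-I arm) over
~4 months with 4–6 model runs each; the
ascent-statistic checks use single 60-day deployments; bootstrap
consistency uses 10,000 tracks on one autumn deployment. The acceptance
script runs a 2-population × 3-bird cohort over a full year with 10 model
runs.

## Known limitations

* The baseline-altitude covariate (`flight_alt`) is mechanically coupled to
  the response: the ascent height subtracts that same baseline, so any
  within-window altitude variance induces a (negative) association even
  when ascents are drawn independently of altitude. Its coefficient should
  be read as descriptive, not causal.
* With rare ascents in a sparsely sampled phase (breeding at 5 %
  probability over a short window) the phase contrast can quasi-separate;
  the fit flags runaway standard errors but keeps the run, since the
  relevance rule is robust to inflated intervals.
* The grid HMM replaces a template-fit likelihood with a twilight-time
  residual likelihood; its posteriors honour the probability-map contract
  that the bootstrap needs, but they are not calibrated against any
  specific tag model.
* Around equinoxes latitude information vanishes; the movement prior keeps
  posteriors proper, and phase probabilities honestly reflect the
  ambiguity (this is why the ensemble redraws tracks at all).
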