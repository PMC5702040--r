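---
title: "Models and methods behind sonarramp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sonarramp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonarramp)
```

`sonarramp` implements the computational chain of a controlled exposure
experiment on sonar ramp-up effectiveness: transmission schedules, received
levels and risk indicators, avoidance-response detection, a Monte Carlo of
full-power exposure outcomes, and the cluster-robust statistics. This
vignette documents the models, their assumptions, the tunable parameters,
and the design decisions taken where the procedure was genuinely open. It
states no empirical result that the package's tests and acceptance script
do not themselves compute.

## Transmission schedules

A session lasts 600 s with one pulse slot every 20 s on the half-open grid
t = 0, 20, …, 580 s. The ramp-up scheme rises from 152 to 214 dB re.
1 µPa m during the first 15 slots and holds 214 dB for the last 15; the
full-power scheme uses only the last 15; a control transmits nothing.

Two open points were resolved as follows:

* **Ramp step sequence.** Only the endpoints and "gradual increase" of the
  ramp are documented, so the default interpolates linearly in decibels
  across the 15 ramp pulses, with the final ramp pulse at 214 dB. The
  `step_rule` argument accepts alternatives (e.g. `"constant"`), so other
  fielded schedules can be expressed.
* **The t = 600 s slot.** The session window is treated as half-open; no
  pulse is emitted at exactly 600 s. This yields 15 + 15 pulse slots and
  keeps consecutive sessions disjoint.

Energetics use the energy source level `SL_E = SL + 10·log10(T/t0)`
(t0 = 1 s) with effective durations T = 0.47 s (ramp phase, 0.5 s pulses)
and T = 0.93 s (full phase, 1 s pulses). With the linear-in-dB default the
ramp-up scheme's total SL_E exceeds the full-power scheme's by about
0.22 dB; the fielded schedule's documented difference, 0.43 dB, is applied
as a fixed `SEL_cum` adjustment for ramp-up sessions
(`adjust_rampup_selcum()`) rather than re-derived, because the exact
fielded step sequence is not tabulated. The adjustment is flagged
idempotent per value so it cannot be applied twice.

## Exposure model

Received levels combine the source level with a propagation loss (PL)
model: `SPL = SL − PL`, `SEL = SL_E − PL`, and
`SEL_cum = 10·log10(Σ 10^(SEL/10))`. PL is a pluggable function; the
shipped default is spherical spreading `20·log10(r)` with optional linear
absorption (dB km⁻¹), and `pl_grid()` reads an externally computed
range × depth PL field (bilinear interpolation, clamped at the grid
edges) for users with ray-trace output. Ray tracing itself, bottom
interaction and sound-speed profiles are out of scope.

Numerical choices:

* Whale and ship positions are interpolated **linearly** to pulse times;
  pulse times outside a track's span are an error naming the offending
  track.
* `R_min` is a proximity metric, not tied to pulses: it is evaluated on
  both tracks interpolated to 1 s resolution over the whole session
  window.
* The received level uses the whale's depth at pulse time; no
  surface-image interference is modelled.
* Zero slant range is rejected as unphysical.

`apply_bias_correction()` adds the mean (measured − modelled) difference —
or a fixed offset — to modelled levels, with offsets maintained separately
per indicator by the caller. `propagate_position_uncertainty()` perturbs
the whale track (isotropic horizontal Gaussian noise; depth noise with a
1 m default s.d. reflecting tag pressure-sensor precision) and reports the
mean and s.d. of the indicators over draws.

## Synthetic data generator

The generator exists so that every downstream stage is testable without
field data; it emulates the statistical structure the analysis assumes,
not any particular animal.

* **Baseline movement** is a correlated random walk on a 20 s grid:
  wrapped-normal heading increments (default s.d. 10° per step),
  truncated-normal speeds (mean 1.0, s.d. 0.3 m s⁻¹, floor 0.05), a
  sinusoidal dive cycle (7 min period, 30 m amplitude) with Gaussian noise
  clipped at the surface, and Poisson feeding lunges (8 h⁻¹) retained only
  when the whale is deeper than 0.5 m.

  The 10° step spread was chosen to represent directed travel in which
  spontaneous ≥90° within-session turns followed by persistent movement in
  one direction are uncommon (about 2% of null sessions) — consistent with
  approach-alone control sessions eliciting no avoidance-like turns in the
  field. This matters because the detector's Bonferroni correction counts
  *candidate* turns (see below): a null whale that circles constantly
  would defeat any detector faithful to that published procedure. The
  parameter is exposed (`baseline_params(turn_sd_deg = …)`), so heavier
  turning regimes can be generated deliberately.
* **Avoidance injection** rotates the heading by a signed angle at onset
  and holds it (directed flight) at a set speed, 1.3 m s⁻¹ by default —
  the average observed avoidance speed. A `"rotate"` rule preserves the
  baseline wiggle instead, and a `"ship_relative"` rule draws the held
  heading at 0–100° relative to the ship course (the detector's
  movement-away band), in which case the realised turn magnitude is
  implied rather than prescribed.
* **Ship approach.** `plan_intercept()` solves the constant-velocity
  pursuit quadratic using a least-squares velocity estimate over the last
  three whale fixes (the field navigation tools were proprietary and used
  different logic; only the 1.25 km start rule is reproduced faithfully).
  No feasible intercept (whale as fast as the ship and diverging) falls
  back to a course at the whale's current position, flagged. Sessions are
  600 s, starts separated by 70 min, control always first.
* **Coordinates** are local flat-earth metres (east/north), headings
  clockwise from north, depths positive down; no geodesy.

What the generator does **not** emulate: tag sensor noise and gaps,
surfacing-dependent fix availability, behavioural-state switching, tidal
drift, or dose-dependent response onset. Passing tests therefore
demonstrate correctness of the pipeline's logic under the stated
assumptions, not field performance on real tracks.

## Avoidance detection

Tracks are downsampled to 20 s (the pulse interval); headings are compass
bearings of successive displacements. A *turn* is a maximal run of
same-sign wrapped heading increments (increments below 10⁻⁹ degrees are
treated as zero so that numerically straight tracks contain no turns);
its magnitude is the absolute sum of the run's increments and may exceed
180°.

A turn is a *candidate avoidance* if its magnitude is ≥90°, it ends inside
the session window, and the mean absolute heading relative to the ship
course over the post-turn steps (to session end; at least 3 steps, 60 s)
lies in [0, 100)°. Candidates receive an empirical p-value against the
turn magnitudes of 4 h of baseline (non-session) data preceding the
session, using the add-one tail proportion
`p = (1 + #{baseline ≥ magnitude}) / (1 + n)`, which cannot reach zero with
a finite baseline. By default the null set uses baseline turns of the
candidate's rotational direction (`direction_matching = "match"`); a
pooled single-direction option exists because the published procedure used
"only turns in one direction" without fixing which.

Calls are made at a Bonferroni-corrected level: `p < α / n_tests`, with
`n_tests` the number of candidate turns across all sessions of the whale's
experiment. With a 4 h baseline (≈175 turns per direction) the smallest
attainable p is ≈1/176 ≈ 0.0057, so the correction tolerates up to eight
tests at α = 0.05 — matching the small candidate counts the procedure
expects. The onset of a response is the start time of its turn; because an
injected or real turn can merge with adjacent same-sign drift, a recovered
turn may begin one or two steps before the true onset with a
correspondingly larger magnitude.

Feeding state is assigned per session: *feeding* if at least one lunge
falls between 10 min before session start and the response onset (or
session end without a response).

## Full-power outcome simulation

The Monte Carlo quantifies how much an instantaneously avoiding whale
could reduce its SPL_max under the full-power protocol. Each draw samples
a whale state at the first full-power pulse (t = 300 s): horizontal range
(truncated normal, µ = 456 m, σ = 185 m, floor 0), angular position
(von Mises, µ = 20°, κ = 0.89), depth (gamma, shape 0.5, scale 37 m,
constant within a draw) and avoidance speed (truncated normal,
µ = 1.3 m s⁻¹, σ = 0.5 m s⁻¹, floor 0). The source runs at 4.1 m s⁻¹ and
50 m depth, one 214 dB pulse every 20 s in [300, 600) s, spherical
spreading without absorption.

Each draw is evaluated **paired**: the same sampled whale is scored
stationary and moving perpendicular to (and away from) the source
trackline from immediately after the first pulse; the reduction is the
difference of the two SPL_max values. Pairing makes a 75th percentile of
exactly zero meaningful; reductions are provably non-negative because
perpendicular-away motion cannot shorten any post-onset slant range, and
are zero precisely when the stationary maximum already occurs at the first
pulse.

Two resolutions of ambiguity are exposed in the configuration:

* **Bearing reference axis.** The default measures the von Mises angle
  from the *reciprocal* of the source course, i.e. whales predominantly
  astern of the source at t = 5 min. This follows from the navigational
  protocol: the predicted ship–whale intercept falls at ≈305 s, and the
  source is towed a further cable length (250–300 m) astern of the ship,
  so the source typically passes the whale early in the full-power phase.
  Under this orientation roughly three quarters of draws cannot reduce
  their SPL_max at all; measuring the angle from the course itself
  (`bearing_axis = "course"`) instead places most whales ahead and
  roughly triples the non-zero fraction.
* **On-line whales.** A whale exactly on the trackline moves to its
  sampled-bearing side.

Truncated distributions are sampled by rejection (the truncation mass is
small for all defaults); von Mises angles use the Best–Fisher
wrapped-Cauchy envelope algorithm, with exact degenerate limits at κ = 0
and κ = ∞. The default 100,000 iterations run in about a second;
percentile estimates are stable to well under 0.3 dB across seeds at that
size.

## Risk statistics

Indicators are analysed with factor models under an **independence working
correlation**, so point estimates are ordinary least squares (Gaussian
family; SPL_max, SEL_cum) or gamma maximum quasi-likelihood (R_min). The
gamma family uses a log link by default — predictions stay positive, and
for the saturated factor designs used here per-level predictions equal
per-level sample means regardless of link. Groups of associated whales,
not individual whales, are the clustering unit.

The coefficient covariance is the **leave-one-cluster-out jackknife**,
`(m−1)/m · Σⱼ (β₍₋ⱼ₎ − β̄)(β₍₋ⱼ₎ − β̄)ᵀ`, preferred over the sandwich
estimator at small cluster counts; with singleton clusters it reduces to
the ordinary delete-one jackknife. A cluster that exclusively carries a
factor level makes the jackknife undefined and is reported as an error
rather than silently dropped.

Contrasts between factor-level combinations use a parametric bootstrap on
the jackknife covariance (default 5000 multivariate-normal coefficient
draws, response-scale prediction differences, 2.5/97.5 percentile
interval); a difference is *significant* when the interval excludes zero.
For large draws these intervals converge to normal-theory intervals, which
the tests verify.

`barnard_test()` is an unconditional two-proportion test: the
pooled-variance score statistic, with the p-value maximised over a uniform
grid (default 1001 points) of the nuisance success probability under
independent binomials. The published analysis names the test but not the
statistic; the score statistic is the common default, and both the
session-level and whale-level 2×2 constructions can be passed since the
function takes raw counts. Degenerate tables (an empty arm) are errors;
tables with zero pooled variance score Z = 0.

Hearing risk classifies weighted `SEL_cum` against TTS onset at 179 and
PTS risk at 199 dB re. 1 µPa² s for low-frequency hearing specialists
(the auditory weighting is 0 dB in the 1.3–2.0 kHz band, so unweighted
sonar values compare directly). A value equal to a threshold takes the
higher-risk class.

## Problem sizes and determinism

The shipped tests exercise the Monte Carlo at its full 100,000 iterations,
the null false-positive property on 500 synthetic experiments (1500
sessions), and parameter recovery on 200 injected responses; module tests
use smaller replicates of the same checks. All stochastic components take
explicit seeds, experiments are byte-identical on disk for a fixed seed,
and every pipeline output records the seed and a configuration hash.

## Known limitations

* Spherical spreading is a deliberately simple default; refraction and
  bottom effects can be supplied only through a precomputed PL grid.
* The avoidance detector inherits the published procedure's selection
  behaviour: the Bonferroni denominator counts candidates, so its
  family-wise error control is predicated on baselines in which large
  persistent turns are rare. Heavy-turning behavioural states (e.g.
  surface feeding in circles) would require a different null.
* The pursuit planner assumes constant whale velocity between fixes and
  ignores navigation latency.
* The jackknife requires every factor level to survive each cluster
  deletion; very small designs with rare levels must be pooled by the
  analyst.
* Modelled full-power outcomes assume behaviour during a control approach
  is unaffected by the (silent) ship to the same degree as during a
  transmitting approach.
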