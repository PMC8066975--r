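---
title: "Scoring multi-touch hand assessments: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring multi-touch hand assessments: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handscore)
```

`handscore` turns raw multi-touch event streams from a tablet into the
outcome measures of a six-exercise hand-function assessment for stroke
survivors, and evaluates those measures with the standard psychometric
battery. This vignette is the package's account of the underlying methods:
the measurement model, the tunable parameters and why their defaults are
what they are, the statistics, what the simulator does and does not emulate,
and the numerical corner cases.

## The measurement model

The universal input is a touch-event stream: records
`(t_ms, pointer_id, phase, x_px, y_px)` with `phase` one of `down`, `move`,
`up`, timestamps in milliseconds from the exercise's start signal, and
coordinates in pixels (origin top-left, y downward — the touch-hardware
convention). Per pointer the phase sequence must be exactly
`down, move*, up`; `validate_events()` enforces this grammar, monotone
timestamps within a lifetime, and screen bounds. Pixels are converted once
to centimetres through a mandatory device profile (`px_per_cm` per axis —
panels are not assumed isotropic, and no default density exists because
every downstream outcome is metric).

Scoring is event-driven. "Concurrent contacts at instant *t*" means pointers
whose `[down, up]` interval contains *t*, closed at both ends; each
pointer's position at *t* is its most recent coordinate at or before *t*.
Because positions are piecewise constant between events, evaluating frames
at event timestamps only is exact — extrema of any frame function are
attained at an event. When several events share a timestamp, position
updates and downs are applied before the frame is evaluated and ups are
applied after it, which is what makes the contact interval closed.

The six scorers:

- **Tapping** counts `down` events with `0 ≤ t < 10 s`. Counting downs (not
  ups) makes the window edge unambiguous: a touch beginning inside the
  window counts, one beginning at exactly 10 s does not.
- **Isolated-finger tapping** counts downs inside the window that land
  within `spot_radius_cm` (default 1.25 cm, about a fingertip pad — no
  published spot size exists) of the calibrated spot **and** occur while at
  least `required_resting_contacts` (default 4, the strict whole-hand
  reading) other pointers are in contact. The count is configurable because
  capacitive panels sometimes merge adjacent fingertips into one contact. A
  resting pointer lifting at the very instant of a tap still counts — the
  closed-interval convention again.
- **Pincer grasp** takes, over every instant with *exactly two* concurrent
  contacts, the Euclidean distance between them, and reports the maximum
  and minimum. Frames with a transient third contact (palm, nail) are
  excluded rather than failing the trial; a trial with no two-contact
  instant at all is unscorable, which is distinct from a zero distance. The
  exercise is untimed; it ends at the last event.
- **Hand opening/closing** computes, over instants with at least
  `min_area_contacts` (default 3) contacts, the **convex hull** area of the
  contact points, reporting max (open) and min (closed). The hull rather
  than the contact-order polygon is a deliberate design choice: it is
  invariant to pointer-id reordering by the hardware, never self-intersects,
  and degrades gracefully — collinear or near-collinear closed-hand frames
  give area 0 instead of an error.
- **Graphomotricity** measures the dissimilarity between the traced curve
  (all contact positions in time order) and a template figure ("M", "3",
  "S", spiral). Both curves are resampled to `grapho_resample_n = 200`
  points equally spaced by arc length, and the dissimilarity is the
  symmetric summed nearest-neighbour distance
  `0.5 (Σ_i d(a_i, B) + Σ_j d(b_j, A))` with distances taken to the full
  polyline, not only to vertices. It is a premetric: non-negative, zero on
  identity, symmetric, rigid-motion invariant. Being a *sum* over 200
  points, values are in the tens of centimetres for visibly deviating
  traces, and scale linearly with the resampling constant — `n` is therefore
  part of the configuration and recorded with the results. For a trace that
  is the template translated perpendicular to a straight segment by *d*, the
  dissimilarity is exactly `n·d`.
- **Oculo-manual coordination** acquires each of 32 targets (4 × 8 grid,
  default layout evenly spaced with a 1.5 cm margin) at the first `down`
  within `target_radius_cm` (default 1.0 cm) of its centre, nearest
  unacquired target first; the outcome is the time of the 32nd distinct
  acquisition, in seconds. Repeat touches on acquired targets do nothing.
  If the 32nd acquisition has not happened within `oculo_timeout_s`
  (default 120 s) the trial is reported incomplete with the count achieved.
  The three conditions (finger, pen, pen with drop-and-grasp) are
  distinguished only by exercise id; their outcome definition is identical.

## The psychometric battery

Reliability uses the two-way random-effects, absolute-agreement,
single-measure intraclass correlation computed from the two-way ANOVA
without replication,

$$\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + k(MS_C - MS_E)/n},$$

implemented directly from the sums of squares (and cross-checked in the test
suite against an independent `aov()` decomposition to 1e-12). Its p-value is
the upper tail of the row-effect F test, \(MS_R/MS_E\) on
\((n-1, (n-1)(k-1))\) df. `reliability_report()` lays an n × 3 score matrix
out as two sessions by rater A plus one by rater B, computes the intra-rater
ICC from columns 1–2 and the inter-rater ICC from the first session of each
rater (columns 1 and 3 — the pairing is a package choice, as conventions
differ), then

$$\mathrm{SEM} = SD \sqrt{1 - \mathrm{ICC}}, \qquad
  \mathrm{MDC}_{95} = 1.96\sqrt{2}\,\mathrm{SEM},$$

with the SD taken over the pooled intra-rater session pair (which SD feeds
the SEM is not standardised; the choice is recorded here so alternates can
be swapped). The identity between MDC95 and SEM is asserted on every report.

Convergent validity is Pearson's r with two-sided p and a strength band from
|r|: excellent (> 0.8), strong (0.6, 0.8], moderate (0.4, 0.6], weak
(0.2, 0.4], very weak (≤ 0.2). Boundaries are half-open with the boundary
value in the lower band (0.8 is "strong"), a convention fixed here because
prose definitions are ambiguous at shared endpoints; magnitudes are used
because validity against time-scored instruments is legitimately negative.
`validity_matrix()` crosses every instrumented measure with every clinical
column, marking pairs with fewer than 3 shared complete observations (or
zero variance) unavailable rather than erroring, and flagging |r| > 0.4.

Outlier screening removes cells with |z| > 3 per measure (two-sided — the
conservative reading of a "beyond three SD" rule) and drops participants
flagged in more than two measures. Severity grouping follows the Fugl-Meyer
Assessment for Upper Extremity: 19–46 moderate, ≥ 47 mild. A literal reading
of the defining ranges ("between 19 and 46", "higher than 47") leaves 47
unassigned; the package classifies 47 as mild in favour of contiguity.
Scores below 19 (severe impairment) are outside the populations such
instruments were validated on and raise an explicit out-of-scope error.
Group comparison is the two-sided pooled-variance Student's t
(df = n₁+n₂−2), with Welch's correction available behind a flag but off by
default.

## The simulator

The simulator exists so that every scorer and statistic can be exercised,
end to end, without patient data. Its outcome model is deliberately
phenomenological: each measure's scored outcome is drawn from a normal
distribution with the group's mean and SD, truncated at physical bounds
(counts and distances ≥ 0; a floor of 2 s for 32-target sweeps; apertures
and areas capped by what physically fits the panel) by resampling, counts
rounded. The default profiles are the published summaries of an
88-participant stroke cohort (69 mild / 19 moderate), all 23 measure rows —
e.g. tapping 43.97 (14.47) vs 25.26 (13.51) per 10 s, maximum index pincer
13.05 (2.04) vs 10.31 (2.29) cm, hand opening 95.47 (23.84) vs 67.88
(25.60) cm². `expected_outcome()` returns the closed-form mean of the
truncated law, which is what a Monte-Carlo mean of scored outcomes converges
to; at mild-range parameters truncation is slight.

Given a drawn target outcome, each generator constructs a grammatically
valid stream that *realises it exactly*: evenly spaced down/up pairs for
tapping; four sustained weight-bearing contacts plus on-spot taps for
isolated tapping; a two-contact radial trajectory passing through the drawn
extrema for pincer; a five-contact pentagon breathing between the radii
implying the drawn open/closed areas (pentagon area `(5/2) r² sin 72°`);
and 32 target touches whose last down lands at the drawn completion time.
The drawing generator translates the template diagonally and inverts a
cached per-template monotone calibration curve (offset magnitude →
dissimilarity) to hit the drawn value; the inversion is piecewise-linear, so
scored drawing outcomes match their targets to well under a percent rather
than exactly. A zero-mean, zero-SD drawing profile reproduces the template
verbatim and scores exactly 0.

What the simulator does **not** emulate: tremor-like within-stroke dynamics,
nail/palm contact artifacts, finger merging on real panels, learning or
fatigue across sessions, missing data patterns, or any biomechanics of the
hand — kinematics are the minimum needed to exercise the scorers. Passing
tests therefore demonstrate that the *pipeline* is correct and that the
statistics recover what the generators encode; they say nothing about how a
particular patient population will behave. One practical interaction worth
knowing: moderate-group pen-drop completion times (mean 163 s) exceed the
default 120 s acquisition timeout, so scoring such simulated trials
requires a raised `oculo_timeout_s` — as it would with comparably impaired
real users.

Reliability data follow the two-way model
\(y_{ij} = \mu + p_i + s_j + e_{ij}\) with independent zero-mean normal
components, so the theoretical ICC(2,1) is
\(\sigma^2_p / (\sigma^2_p + \sigma^2_s + \sigma^2_e)\). Cohort tables draw
FMA-UE scores uniformly within each group's defining range (only group
summaries are published, and uniformity is the least-informative choice on
a bounded range) and build clinical columns as
\(\rho z + \sqrt{1-\rho^2}\,\varepsilon\) against a standardised outcome, so
the configured \(\rho\) is the population validity coefficient.

## Numerical choices and degenerate inputs

- Hull area uses `chull()` plus the shoelace formula; fewer than three
  non-collinear points give 0, never an error. Empty point sets error.
- Arc-length resampling pins both endpoints and interpolates within
  segments; zero-length polylines error. Consecutive duplicate points are
  collapsed when a polyline is constructed.
- Point-to-polyline distance clamps the projection parameter to each
  segment, so interior projections and vertex fallbacks are handled
  uniformly.
- Event streams are stably sorted by timestamp, so simultaneous events keep
  their serialisation order; scoring results are invariant to
  re-serialisation at equal timestamps because frames are evaluated after
  all updates at that timestamp.
- All simulation functions take explicit seeds, derive nothing from global
  state, and restore the caller's RNG stream.
- Zero-variance inputs error in `icc_2_1()` and `pearson_validity()`
  (undefined quantities), but only warn-and-skip in `remove_outliers()`
  (a constant measure is valid data).

## Validation scale

The package's own validation (test suite and `scripts/acceptance.R`) runs
at sizes chosen to make Monte-Carlo error small relative to the effects
checked: 500 scored sessions per exercise for mean recovery, 500 simulated
69/19 cohorts for the severity-sensitivity pattern, 200 replicates of
n = 500, k = 2 two-way data for ICC parameter recovery, and 1000-case
geometry fuzzes against brute-force oracles. These complete in about a
minute on a single core.

## Known limitations

- The hand-area and drawing-dissimilarity estimators are this package's own
  re-specifications of outcome definitions whose original estimators are
  not publicly documented; absolute values of these two measures should not
  be compared across implementations without cross-calibration (the
  dissimilarity additionally scales with `grapho_resample_n`).
- The scorers do not attempt to identify which anatomical finger produced a
  pointer; exercises that are per-finger rely on the protocol, not the
  data, for that attribution.
- `remove_outliers()` applies the z-rule once, not iteratively; with very
  small cohorts a masked outlier can survive.
- The simulator's outcome-level normality is an assumption of convenience;
  skewed real distributions (times, dissimilarities) will differ in the
  tails.
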