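# handscore

Scoring and psychometric evaluation of multi-touch hand assessments.

After a stroke, hand mobility and dexterity are usually rated with clinical
scales that can lack accuracy and specificity. A capacitive tablet can
measure finger contacts directly: a test battery of six on-screen exercises
— finger tapping, isolated-finger tapping with the other digits
weight-bearing, finger–thumb pincer apertures, hand opening/closing, figure
tracing, and timed acquisition of a 4 × 8 target grid — yields objective
outcome measures of hand function. `handscore` is an open toolkit for
researchers and rehabilitation engineers working with such instruments. It
provides:

- **Event-stream scoring.** Raw multi-touch logs (timestamped pointer
  `down`/`move`/`up` records in pixels, plus a device profile in px/cm) are
  validated against the per-pointer phase grammar and scored into the
  exercises' outcome measures: tap counts in a 10 s window, valid isolated
  taps (inside a calibrated spot while ≥ 4 other digits stay in contact),
  maximum/minimum pincer distance over exactly-two-contact instants (cm),
  maximum/minimum convex-hull area of ≥ 3 contacts (cm²), trace–template
  dissimilarity for the figures "M", "3", "S" and a spiral (cm), and time to
  acquire all 32 coordination targets (s).
- **The psychometric battery** used to validate such instruments:
  Pearson convergent validity with strength bands (|r| > 0.8 excellent,
  0.6–0.8 strong, 0.4–0.6 moderate, 0.2–0.4 weak, ≤ 0.2 very weak);
  two-way random-effects absolute-agreement single-measure intraclass
  correlation,

  ICC(2,1) = (MS_R − MS_E) / (MS_R + (k−1) MS_E + k (MS_C − MS_E)/n);

  standard error of measurement SEM = SD·√(1 − ICC); minimal detectable
  change MDC95 = 1.96·√2·SEM; |z| > 3 outlier screening with removal of
  participants flagged in more than two measures; severity grouping by the
  Fugl-Meyer Assessment for Upper Extremity (19–46 moderate, ≥ 47 mild); and
  pooled-variance Student's t-tests between severity groups.
- **A seeded simulator** that generates grammatically valid touch streams
  whose scored outcomes follow configurable group distributions (defaults
  match a published 88-participant stroke cohort, e.g. mild-group tapping
  43.97 ± 14.47 taps/10 s), plus cohort outcome/FMA/clinical tables and
  two-way reliability data with controllable variance components — so every
  scorer and statistic is testable without patient data.

## Worked example

```r
library(handscore)

# simulate one mild-profile pincer trial and score it
session <- simulate_stream("pincer_index", profile = impairment_profile("mild"), seed = 42)
score_session(session)
#>   participant_id exercise_id  measure_name  value units session_idx rater_id
#> 1 sim            pincer_index pincer_max_cm 11.9  cm              1 A
#> 2 sim            pincer_index pincer_min_cm  2.28 cm              1 A

# reliability of a measure over 23 participants, two sessions by rater A
# plus one by rater B (columns share participant effects)
y <- simulate_reliability(23, 3, mu = 40, vc = variance_components(9, 0.5, 0.5), seed = 7)
reliability_report(y, "tap_count")
#>     measure icc_intra icc_intra_p icc_inter icc_inter_p  sem mdc95  n k
#> 1 tap_count     0.823    4.09e-16     0.938    5.46e-16 1.55  4.28 23 2

# severity sensitivity on a simulated 69/19 cohort
cohort <- simulate_cohort(n_mild = 69, n_moderate = 19, seed = 11)
grp <- cohort$fma$group
compare_groups(cohort$outcomes$tapping[grp == "mild"],
               cohort$outcomes$tapping[grp == "moderate"])
#> tapping: mild 41.32 vs moderate 25.58, t(86) = 4.72, p = 8.9e-06
```

The pincer record gives the widest and narrowest finger–thumb aperture
reached during the trial. In the reliability report, the intra-rater
ICC(2,1) of 0.823 sits in the "excellent" band, and the MDC95 of 4.28 taps
means an individual change smaller than ~4 taps is indistinguishable from
measurement error. The t-test shows the simulated mild group out-taps the
moderate group by ~16 taps, a highly significant separation.

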