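---
title: "Methods: IMU placement selection and ski-turn performance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IMU placement selection and ski-turn performance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skiturns)
```

## The problem

A ski turn is, to first order, a roll motion: the skier leans into the arc,
and the centripetal force that holds the turn comes from that lean. The
lean also shifts weight onto the outer foot, which is why insole pressure
sensors are the accepted reference instrument for turn analysis — but they
are impractical for daily training (race boots leave no room for pads). A
single IMU is practical; the question is where to put it so that its roll
angle is a faithful surrogate for the weight-shift pattern, and what the
resulting signal supports statistically.

`skiturns` answers this in two stages: a *placement* stage that scores
candidate body locations against the foot-pressure reference, and a
*performance* stage that quantifies lateral asymmetry and the adaptation
trend from the selected location's signal.

## Placement selection

**Pattern correlation.** Per trial, the foot-pressure ratio
r = (F_L − F_R)/(F_L + F_R) is formed from the summed 13-cell insole
forces, smoothed with a 5-point centered moving average, linearly
resampled from the 50 Hz insole grid onto the 100 Hz IMU grid, and
standard-score normalized (n − 1 denominator throughout). Each location's
roll trace receives the same smoothing and normalization, and the Pearson
correlation ρ_l per location × trial fills a table whose per-location
median R_l is the fidelity summary (the median resists a single corrupted
trial, which matters at eight trials).

Two conventions deserve attention because the field's reports leave them
implicit:

- *Ratio sign.* We define r so it is positive when the left foot is
  loaded. A right turn (positive roll, lean right) loads the left (outer)
  foot, so roll and ratio co-vary positively and good locations score
  positive correlations. Had the opposite sign been chosen, every
  correlation would flip sign; the normalization makes no other
  difference.
- *Rate reconciliation.* Correlation needs both series on one grid. We
  upsample the pressure ratio to the IMU grid (linear interpolation, no
  extrapolation past the last sample) rather than downsampling the IMU,
  preserving the denser signal.

**Clustering.** Locations are clustered by correlation distance with
centroid linkage, d(r, s) = |x̄_r − x̄_s|. The default "reference" mode
places each location at the scalar coordinate 1 − R_l with the
foot-pressure reference as a leaf at 0, since R_l is defined *against the
reference*; a "pairwise" mode accepts a full signal-by-signal correlation
distance matrix for the alternative reading where the sensors are compared
to one another. The linkage is implemented via the Lance–Williams centroid
update on squared distances, which on scalar coordinates reproduces the
absolute difference of cluster means exactly; ties in the minimum distance
are broken toward the earliest cluster pair, which makes the merge order
deterministic. On a line, centroid linkage cannot produce height
inversions (the merged centroid lies between its parents), so reference-
mode dendrogram heights are monotone; in pairwise mode the usual centroid
caveat applies and `as.hclust()` clamps heights for plotting only.

**Turn detection.** A turn is a maximal run of constant roll sign; a
sample exactly at zero closes the preceding run (deterministic,
boundary-exact). The detection measure is detected/actual × 100, rounded
to integer percent, so 100 is attainable only by exact agreement. Raw
crossing counting (`min_duration_s = 0`) is what field reports tabulate;
values above 100% in such tables show that jitter crossings occur in
practice. For everything downstream of detection the package uses
`min_duration_s = 0.5` s: runs shorter than half a second — well below any
credible giant-slalom turn (~1.4–3 s) — are merged into the following run
and same-sign neighbours coalesce, so a brief noise blip near a zero
crossing never splits a turn.

**Ranking.** A location passes if R_l ≥ 0.80 (the conventional bound for a
strong correlation) *and* detection is 100% in every trial. Among passing
locations: higher median correlation first, then single midline placements
(head, spine, pelvis) over left/right pairs, then alphabetical order. The
sensor-count rule is a computable proxy for the practical criteria —
attachment effort and athlete distraction — that favour one midline
sensor; those criteria are otherwise survey-based and not computable here.

## Performance statistics

**Turn table.** Per segmented turn: duration (samples/rate) and the
maximum outer-foot pressure fraction, (1 + r)/2 over right turns and
(1 − r)/2 over left turns. Trials whose segment count disagrees with the
expected turn count are excluded and logged, mirroring how a corrupted
attempt is handled in practice.

**Lateral asymmetry.** For each measure the two sides are screened with a
one-sample K-S test against a normal with the group's estimated mean and
SD — with estimated parameters the nominal p-value is conservative (the
Lilliefors caveat), acceptable for a screen — and with a two-sided F test
of variance equality at the same α. Equal variances route to the pooled
statistic (df = n_L + n_R − 2); unequal to Welch. The F test was chosen
over Levene/Bartlett as the textbook companion of the t-test at these
sample sizes; it is exposed as its own function so a different screen can
be substituted. Decisions compare |t| against the two-sided critical point
t_{α/2}(df), the same rule as |t| exceeding the tabulated value.

Welch df are kept real-valued for p-values but *reported* as the integer
part (e.g. 35.2 → 35), matching how critical points are read from a t
table; the critical point uses the reported df. When both groups have zero
variance the F screen returns "equal" trivially; the pooled statistic is
then 0 for equal means and an explicit error for unequal means, since no
scale exists to judge the difference.

**Adaptation.** Attempt index versus total trial duration: Pearson r, an
OLS line, and the t = r√(n−2)/√(1−r²) significance test. Attempts without
a recording keep their position on the attempt axis — adaptation depends
on how many runs the athlete has made, not on how many were recorded — but
contribute no point.

## The synthetic generator

`simulate_session()` produces sessions with the statistical structure the
analyses assume, plus ground truth for recovery tests:

- *Roll:* one half-sine lobe per turn, alternating sign, starting with a
  right turn. Sampling is offset half a step so in-turn samples are
  strictly nonzero and ground-truth boundaries are exact sample indices.
  Durations are drawn per turn around the side mean plus the adaptation
  drift, then quantized to whole IMU samples.
- *Insoles:* the outer foot's share of a constant two-foot total rises
  from 0.5 to a per-turn peak by a raised cosine and returns — smooth,
  mid-turn peak, and simple enough that the expected maximum ratio equals
  the configured peak.
- *Fidelity:* per location, trace = gain × latent + Gaussian noise
  (+ an optional 2 Hz sinusoid for arm/hand swing artifacts).

Defaults reproduce the observed study conditions: 8 trials of 6 turns,
100 Hz IMU / 50 Hz insoles, side mean durations 2.08 s (right) and 1.68 s
(left) with SD 0.32 s, outer-foot peak fractions 0.86 (left turns) and
0.81 (right turns) with SDs 0.05 and 0.09 — the unequal spread is what
exercises the Welch branch — and an adaptation slope of −0.047 s per turn
per attempt (−0.28 s per 6-turn trial). Quantities no report states are
free parameters chosen once: roll amplitude 30° (a typical racing lean),
two-foot total 40 N/cm² summed over cells, per-cell noise 0.1 N/cm², and
the location noise ladder — pelvis 1°, spine 3°, thigh 4°, shank/foot 5°,
head 8°, arms/hands gain 0.6 with 8–12° noise plus the 2 Hz artifact. The
ladder encodes distally increasing ski-transmitted vibration (the pelvis,
near the centre of mass, is mechanically damped; feet sit on the source),
which yields the published fidelity ordering with the pelvis on top.

Because the half-sine roll and raised-cosine loading are deliberately
different waveforms, the noiseless pattern correlation is not 1 but
cor(sin, sin²) on (0, π) = (4/3π)/√(3/16) ≈ 0.9801 — the tests pin this
analytic value. What the generator does *not* emulate: terrain and gate
geometry, carving-specific edge dynamics, sensor drift (handled inside
commercial sensor fusion), pitch/yaw coupling, or non-Gaussian outliers
from pole plants and compressions. Passing tests therefore demonstrate the
pipeline's statistical behaviour under its stated model, not robustness to
every artifact of real snow data.

## Numerical choices and degenerate inputs

- Moving-average edges use truncated (shrinking) windows, so output length
  equals input length; even windows are rejected rather than silently
  recentred.
- `zscore` refuses constant series by name; correlation refuses constant
  inputs; the pressure ratio flags samples whose two-foot total falls
  below 1 N/cm² (no weight information) and errors on an all-zero stream.
- Trace CSVs tolerate 1% timestamp jitter silently and regularize larger
  monotone jitter with a warning; non-monotone time is a structured error
  with the line number.
- The packaged reference tables are checksum-verified on load.
- All randomness flows through one seeded generator per session;
  identical seeds give byte-identical session files.

## Test problem sizes

The Monte-Carlo tests use the generator's turn-parameter path (durations
and peaks without waveform synthesis) where only turn-level statistics
matter: 1000 null replicates for the type-I error of the branched
asymmetry test (accepted band 2–9% at α = 0.05), 200 replicates for power
at the default asymmetry (≥ 80% on segmentation-recovered durations), 100
two-trial replicates for side-mean recovery within two standard errors,
and 200 sixteen-attempt replicates for the no-spurious-trend null check —
at eight attempts the null probability of |r| < 0.5 is only 0.79
analytically, so sixteen is the smallest round size where a 90% bound is
meaningful. Parameter-recovery and power tests set the adaptation slope to
zero so the configured side means are the estimands.

## Limitations

Single-subject study conditions are baked into the defaults; nothing here
generalizes across athletes. The pressure-ratio sign convention and the
50→100 Hz upsampling are documented choices where field reports are
silent. The max-pressure-ratio asymmetry has modest power at the default
effect size (analytically ≈ 0.65 at n = 24 per side), so a retained null
on that measure is weak evidence of symmetry. The comfort/distraction
criteria behind placement choice enter only through the midline-first tie
rule.
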