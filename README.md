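# skiturns

Where should a single wearable IMU sit on an alpine skier's body so that its
roll-angle signal captures turn motion, and what can that signal say about
performance? `skiturns` implements the full analysis pipeline for this
question, aimed at sports scientists and wearable-device engineers working
with on-snow training data:

1. **Sensor-placement selection.** Roll-angle traces from up to 16 body
   locations are compared against the weight-shift pattern measured by
   13-cell insole pressure sensors — the accepted reference for turn motion.
   Each trace and the foot-pressure ratio are smoothed (5-point moving
   average), standard-score normalized, and correlated per trial
   (Pearson ρ(F, M_l)). Locations are clustered by correlation distance
   1 − R_l (R_l = per-location median correlation) with centroid linkage
   d(r, s) = |x̄_r − x̄_s|, and screened by a zero-crossing turn-detection
   measure (detected/actual × 100%). Strong correlation (R_l ≥ 0.80) plus
   perfect detection, with single midline placements preferred over
   left/right pairs, selects the placement — the pelvis, under realistic
   conditions.
2. **Turn performance.** From the selected trace, turns are segmented at
   zero crossings of the roll angle (positive roll = right turn). Per turn:
   duration and maximum outer-foot pressure ratio. Lateral asymmetry is
   tested with two-sample t-tests (H0: μ_L = μ_R) whose variant —
   pooled-variance T = (μ̂_L − μ̂_R)/(S_p √(1/n_L + 1/n_R)) or Welch
   T = (μ̂_L − μ̂_R)/√(s_L²/n_L + s_R²/n_R) with Welch–Satterthwaite df —
   is chosen by an F test of variance equality after K-S normality
   screening. The adaptation effect is the correlation between attempt
   index and total trial duration.
3. **Synthetic sessions.** `simulation_config()` / `simulate_session()`
   generate sessions with known ground truth: alternating half-sine roll
   lobes, a raised-cosine outer-foot weight shift, per-location fidelity
   profiles, a configurable left/right asymmetry and adaptation trend. Every
   stage of the pipeline is testable without any recorded data.

## Worked example

The package ships the published reference tables as fixtures: the 48-turn
performance table (8 trials × 6 turns) and the 9-attempt record (attempt 2
was discarded during data collection).

```r
library(skiturns)

t4 <- load_fixture("table4")
asymmetry_analysis(t4)
#> <asymmetry_analysis> H0: mu_L = mu_R, alpha = 0.05
#>   duration_s         pooled |t| = 4.27, df = 46, t_crit = 2.01 -> H0 rejected
#>   max_pressure_ratio welch  |t| = 2.71, df = 35, t_crit = 2.03 -> H0 rejected

t6 <- load_fixture("table6")
adaptation_analysis(t6$attempt, t6$total_duration_s)
#> <adaptation_result> r = -0.696 over 8 attempts (df = 6)
#>   OLS: duration = 12.805 -0.282 x attempt; t = -2.37, p = 0.05531
```

Turn durations are asymmetric (right turns are ~0.4 s slower than left, a
pooled t of 4.27 on 46 df versus a critical point of 2.01), and so is the
outer-foot loading, where the F test finds unequal variances and routes to
the Welch statistic (35 reported df). The adaptation correlation of −0.696
means trial totals shrank by ~0.28 s per attempt as the skier acclimated.

The same analyses run end to end on synthetic data:

```r
rep <- run_pipeline(simulation_config(seed = 11))
rep$placement$selected
#> [1] "pelvis"
head(rep$placement$ranking[, 1:5], 3)
#>      location median_correlation strong_correlation perfect_detection midline
#> 1      pelvis          0.9653764               TRUE              TRUE    TRUE
#> 2 lower_spine          0.9647893               TRUE              TRUE    TRUE
#> 3 upper_spine          0.9645343               TRUE              TRUE    TRUE
```

`report_json()` and `report_markdown()` serialize the full report, including
every equation-level intermediate (group means, variances, S_p, exact and
reported df) and the dendrogram in Newick form.

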