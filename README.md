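# bowfreeze

Joint-freezing surrogate analysis of string-instrument bowing kinematics.

## The problem

Skilled cello bowing demands the coordination of many degrees of freedom:
the bow must be transported across the string with large amplitude, at
near-constant velocity, while the bow–string angle is held close to 90° and
bow direction reverses quickly at every stroke boundary. Which joints of
the right arm contribute to which aspect of this performance — and whether
a joint *contributes motion* or *coordinates with the others* — cannot be
read off joint-angle time series directly.

`bowfreeze` implements a counterfactual ("freezing") analysis for
marker-based motion capture of bowing. A measured trial is decomposed into
a kinematic chain of per-frame rigid-body motions (scapula root pose, then
shoulder, elbow, and wrist joints, then the hand–bow grip), each joint
expressed in its proximal neighbour's marker-derived local coordinate
system. Surrogate trials are generated by holding one joint's 6-DoF
configuration constant while everything else moves as measured, markers are
reconstructed from the modified chain, and bow performance is re-scored.
The central quantity is, per joint *j* and performance measure *m*,

```
effect(j, m) = log10( m(surrogate with j frozen) / m(original) )
```

so negative values mean freezing the joint degrades (reduces) the measure
and positive values mean the frozen variant scores higher. For variability
measures this sign logic is diagnostic: with independent joints, removing
motion can only remove variance, so an *increase* in (say) bow-angle SD
under freezing certifies that the joint was coordinated with the others to
stabilize that variable.

Five measures are scored per bow direction: movement amplitude (mm),
bow-angle SD (degrees, central 80% of each stroke), within-bow velocity
variance, between-bow velocity variance ((mm/s)², central 80%), and
reversal acceleration amplitude (mm/s², 45-sample windows around each
reversal). The inferential layer mirrors the study design: one-sample
t-tests of log-ratios against 0 with Holm adjustment, and Type-II
Group × Lab ANOVA for expert/novice comparisons.

Because no human recordings are distributed, the package includes a
joint-space motion generator (`simulate_trial()`, `coordination_preset()`)
that synthesizes all 14 marker roles through the same forward model the
analysis inverts, with expert-like, novice-like, and
coordination-null/compensatory presets — providing exact ground truth for
every pipeline stage.

## Worked example

```r
library(bowfreeze)

sim <- simulate_trial(coordination_preset("expert_like"), seed = 42,
                      meta = list(participant_id = "E01",
                                  group = "expert", lab = "B"))
res <- run_freezing_analysis(sim$trial)
subset(res$effects, measure %in% c("amplitude", "angle_sd"))
```

```
    joint   measure direction original surrogate log10_ratio
 shoulder amplitude      down   352.06     22.20      -1.200
 shoulder amplitude        up   352.07     22.74      -1.190
 shoulder  angle_sd      down     1.06     12.18       1.061
 shoulder  angle_sd        up     1.04     12.10       1.068
    elbow amplitude      down   352.06    273.79      -0.109
    elbow amplitude        up   352.07    273.42      -0.110
    elbow  angle_sd      down     1.06      2.94       0.444
    elbow  angle_sd        up     1.04      2.97       0.458
    wrist amplitude      down   352.06    503.04       0.155
    wrist amplitude        up   352.07    502.90       0.155
    wrist  angle_sd      down     1.06     17.02       1.207
    wrist  angle_sd        up     1.04     16.90       1.213
```

Reading the table: this expert-like trial transports the bow ~352 mm per
stroke with a bow-angle SD around 1°. Freezing the shoulder collapses
transport to 22 mm (log10 ratio −1.2) — the shoulder carries most of the
transport. Freezing the elbow also reduces amplitude. Freezing the wrist
*increases* amplitude to 503 mm: the wrist performs a counter-movement
that brakes transport — and the same frozen wrist inflates bow-angle SD
seventeen-fold (log10 ratio +1.2), showing the counter-movement is what
keeps the bow–string angle stable.

## The analysis workflow

The numbered scripts under `analysis/` reproduce the full study on
simulated data and write their tables under `results/`:

1. `01_simulate_cohort.R` — 10 expert-like + 10 novice-like participants
   across two labs (120 Hz and 60 Hz), written as wide-TSV trials.
2. `02_freezing_analysis.R` — the freezing pipeline per participant →
   `results/freeze_effects.tsv` (one row per participant × joint ×
   measure × direction).
3. `03_stats.R` — within-group t-tests (Holm-adjusted) and Group × Lab
   Type-II ANOVAs → `results/stats_*.tsv`.
4. `04_figures.R` — bar-chart summaries of the log10 ratios per measure.

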