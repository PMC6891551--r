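# gaitsym

Gait asymmetry features from foot marker trajectories, and their
association with general mental health scores.

`gaitsym` is for movement-analysis and ageing researchers who record
overground walking with a minimal marker set — one heel and one toe
marker per foot, sampled at ~100 Hz by optical motion capture — alongside
the 12-item General Health Questionnaire (GHQ-12). It turns raw marker
trajectories into the standard per-subject gait feature table and runs
the cohort-level association analysis, with every stage validated against
a built-in synthetic gait generator that knows its own ground truth.

## What it computes

Per subject, from four marker trajectories:

* **step length** — anterior heel-heel displacement at heel contact (m)
* **step width** — |mediolateral heel-heel displacement| at heel contact (m)
* **double support time** — heel contact → contralateral toe off (s)
* **minimum foot clearance (MFC)** — lowest mid-swing toe height above
  the walking surface (cm); low and variable MFC marks tripping risk

each summarized as mean and intra-subject SD (sample SD over step
cycles), per side and pooled, plus the left-right **Symmetry Index**

    SI = |R − L| / ((R + L)/2) × 100  (%)

applied to both the mean and the SD of each parameter — 16 features.
GHQ-12 responses are scored bimodally (0-0-1-1: "agree"-side items count
1 point, total 0–12, higher = worse general mental health). The cohort
stage computes Pearson correlations of each feature with the GHQ-12
total and an OLS regression of the total on all 16 features plus age
(17 predictors).

Events are detected kinematically: heel contact as the near-floor local
minimum of filtered heel height with a descending approach; toe off as
the last upward zero crossing of toe vertical velocity before the swing
lift-off. All trajectories are smoothed with a zero-phase (dual-pass)
6 Hz Butterworth filter first. Thresholds live in `pipeline_config()`.

## Worked example

Simulate one subject with a programmed clearance asymmetry (left 1.9 cm,
right 1.4 cm), run the pipeline stages, and read off the features:

```r
library(gaitsym)

spec  <- subject_gait_spec(mfc_cm = c(L = 1.9, R = 1.4))
sim   <- simulate_trial(spec, seed = 7)
trial <- preprocess_trial(sim$trial)

events <- detect_events(trial)
events
#> <gait_events> @ 100 Hz  L: 30 HC / 29 TO   R: 30 HC / 29 TO

steps <- segment_steps(events)
rec   <- compute_step_metrics(trial, steps)
mfc   <- compute_mfc(trial, events, ground_ref = "absolute")
summ  <- summarize_subject(rec, mfc, subject_id = "S1")
summ
#> <subject_gait_summary> S1: 29 L + 29 R steps
#>       parameter mean_L    sd_L  mean_R    sd_R mean_pooled sd_pooled
#>     step_length 0.6600 0.03331 0.66461 0.03178     0.66232   0.03235
#>      step_width 0.1187 0.02872 0.11975 0.03065     0.11925   0.02944
#>  double_support 0.0969 0.01561 0.09793 0.01800     0.09741   0.01671
#>             mfc 1.8623 0.56130 1.42807 0.49990     1.64516   0.57051

round(si_features(summ), 2)
#>    si_mean_step_length     si_mean_step_width si_mean_double_support
#>                   0.69                   0.84                   1.06
#>            si_mean_mfc      si_sd_step_length       si_sd_step_width
#>                  26.39                   4.71                   6.52
#>   si_sd_double_support              si_sd_mfc
#>                  14.26                  11.57
```

The spatial and temporal parameters come out symmetric (SI ≈ 1%), while
the programmed clearance asymmetry appears as `si_mean_mfc` ≈ 26% —
the hand value for the programmed sides is SI(1.4, 1.9) = 30.3%, and the
extracted 26.4% reflects the stride-to-stride clearance variability of
this single 30-stride trial.

At cohort scale, with the default latent coupling between mental-health
burden and gait asymmetry:

```r
co    <- simulate_cohort(cohort_spec(n_subjects = 126), seed = 1)
feats <- extract_features(co)
res   <- analyze_cohort(feats, co$ghq, co$subjects)

head(res$correlations[order(-abs(res$correlations$r)), ], 3)
#>               feature    r       p   n significant
#>        step_length_sd 0.57 4.6e-12 126        TRUE
#>   step_length_si_mean 0.55 2.3e-11 126        TRUE
#>      step_width_si_sd 0.53 1.5e-10 126        TRUE

res$regression[c("r", "r_squared", "df1", "df2")]
#> $r        0.7359
#> $r_squared 0.5416
#> $df1      17
#> $df2      108
```

`run_pipeline()` wraps these stages and writes `features.csv`,
`correlations.csv`, `regression.json` and a manifest (inclusion and
exclusion reasons, warning counts) to an output directory; a thin
command-line wrapper with `simulate` / `extract` / `analyze` / `run`
subcommands lives in `inst/cli/gaitsym.R`. See the vignette
(`vignettes/gait-asymmetry-pipeline.Rmd`) for the methods and the design
rationale, including how the synthetic generator programs clearance as a
post-filter observable.

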