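# fcnf

Simulation and analysis tools for **functional-connectivity neurofeedback
(fc-NF)** experiments, in which adolescents (or any scanner-ready humans)
watch a thermometer that displays, in real time, the coupling between their
prefrontal cortex (PFC) and amygdala, and try to push that coupling toward
negative values by emotion regulation.

The quantity fed back is a **moving-window partial correlation**: at every
acquired volume *t*, the Pearson correlation between the PFC and amygdala
signals over the last *L* = 20 volumes, after removing the linear
contribution of a control region in the corticospinal tract (CST),

r_p = (r_xy − r_xc · r_yc) / √((1 − r_xc²)(1 − r_yc²)),

is mapped to a ten-segment thermometer by linear quantization between 0 and
the implementation's upper bound (−1, −0.3 or +1 for the *negative*,
*weighted negative* and *positive* implementations; a one-segment change
corresponds to a correlation change of 0.1, 0.03 and 0.1 respectively).
Runs alternate fc-NF mini-blocks with no-NF mini-blocks in which the display
is frozen at 6/10 segments, so the number of fc-NF volumes inside the moving
window rises 1, 2, …, 20 across a mini-block and falls again during no-NF —
the bookkeeping on which the group analysis rests.

The package provides, end to end and without any scanner data:

- **schedule engine** — block-design run schedules, per-volume window
  composition, counterbalanced start conditions;
- **fc engine** — the streaming partial-correlation computation and the
  three thermometer mappings;
- **synthetic generator** — ROI time series with block-dependent
  PFC–amygdala coupling, AR(1) structure, a shared nuisance channel, and
  cohort covariates (STAI-S/T anxiety, TCAQ thought control, PFC/ACC GABA)
  linked to the connectivity parameters;
- **subject metrics** — initial fc, practice-related slope across runs,
  fc-NF-effect (no-NF minus fc-NF), per-position profiles;
- **group statistics** — profile-vs-window-count correlations, Fisher
  r-to-z comparison of correlations, Pearson correlations with
  bootstrapped-Mahalanobis multivariate outlier removal, t-tests;
- **moderation** — the mean-centered three-way moderation model
  (X = STAI-S, W = PFC GABA, Z = ACC GABA, Y = fc-NF-effect) with simple
  slopes at ±1 SD.

## Worked example

```r
library(fcnf)

sched <- build_run_schedule(20, 7, 20, 20, "fcnf")   # 300-volume run
cfg   <- feedback_config("weighted_negative")
cfg
#> feedback config: weighted_negative (bounds [0, -0.3], 10 segments of 0.03, frozen 6/10, L = 20)

window_composition(sched, t = 21, L = 20)$n_fcnf     # 1  (ratio 1:19)
window_composition(sched, t = 40, L = 20)$n_fcnf     # 20 (ratio 20:0)

sim <- simulate_cohort(cohort_params(n_subjects = 20, seed = 7), sched, n_runs = 4)
cm  <- cohort_metrics(sim$timeseries, sim$schedules, cfg)
gp  <- group_profile(cm$profiles, sched)
profile_vs_count(gp, "mean_fc")
#> $r [1] -0.9929  $n [1] 40  $p [1] 5.1e-32
profile_vs_count(gp, "n_negative")
#> $r [1] 0.9708   $n [1] 40  $p [1] 5.2e-24
```

The two headline numbers say: across the 40 profile points (20 per-volume
positions × 2 conditions), the more fc-NF volumes the moving window
contains, the more negative the group-average connectivity (r ≈ −0.99) and
the more often the windowed partial correlation is negative (r ≈ +0.97) —
the signature of an effective negative-reinforcement implementation. The
same cohort's subject-level measures feed the brain–behaviour correlations
and the GABA moderation model:

```r
joined <- dplyr::left_join(cm$metrics, sim$covariates, by = "subject")
fit <- fit_model3(joined$stai_s, joined$gaba_pfc, joined$gaba_acc, joined$fcnf_effect)
fit$df1; fit$df2
#> 7   12
simple_slopes(fit)          # X-on-Y slope at the 9 (±1 SD, 0) GABA combinations
```

A full pipeline (simulate → stream → metrics → group stats → moderation),
writing every intermediate table plus a JSON report, runs with

```r
run_pipeline(default_config("exp2", seed = 1), "out/")
```

and a thin CLI wraps the same functions
(`Rscript inst/cli/fcnf.R run --out out/ --seed 1`; subcommands `simulate`,
`feedback`, `metrics`, `groupstats`, `moderate`).

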