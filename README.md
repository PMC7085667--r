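# habitspectra

Sensor-based behavioral phenotyping: do people who *perform their daily
activities similarly* also *report similar personalities*?

`habitspectra` implements the full analysis chain for that question, starting
from ordered, timed activity logs (the output of any simple smart-home
activity-recognition system, or a caregiver's diary):

1. **Behavioral spectrum encoding.** A trial — the ordered events
   $(\mathrm{id}_k, d_k)$ observed in a $W$-minute window over an
   $M$-activity vocabulary — becomes a 200-point periodic signal
   $$s_n = a_0 + \sum_{k=1}^{K} \tfrac{d_k}{W}
     \cos\!\big(\tfrac{2\pi k n}{N} + \tfrac{2\pi\,\mathrm{id}_k}{M+1}\big),$$
   with $a_0 = \sum_k d_k / W$: sequence position → frequency, duration →
   amplitude, activity identity → phase. The encoding is exactly invertible
   (`decode_spectrum()`).
2. **Variability features.** Five order-insensitive summaries per spectrum:
   mean, population SD, variance, circular lag-1 autocorrelation, spectral
   entropy.
3. **Habit clustering.** Deterministic best-of-restarts k-means
   (`kmeans_fit()`), uncentered explained-variance curves with elbow-based
   model selection, and MAE-based assignment of new spectra to habits.
4. **Personality scoring.** Ten-item TIPI responses → big-five scores
   (published keying, neuroticism = 8 − stability), sliced into three feature
   modes: all five traits, extraversion + neuroticism, neuroticism only.
5. **Association.** Both sides clustered into two groups; agreement reported
   as an association rate (≥ 0.5 after optimal label alignment) and a phi
   coefficient with a t-transform p-value, one row per
   (period × mode × feature) cell.
6. **Synthetic cohorts.** A generator with a tunable coupling between latent
   neuroticism and activity-switching rate, so the whole pipeline is testable
   end to end without access to (rarely shareable) real cohorts.

## Worked example

```r
library(habitspectra)

# Breakfast for 30 min, then TV for an hour, in a 120-minute window.
v   <- default_activity_vocab()
tr  <- trial("s1", "t1",
             data.frame(seq_index = 1:2, activity = v$activity[1:2],
                        activity_id = 1:2, duration_min = c(30, 60)),
             window_min = 120)
cfg <- encoding_config(window_min = 120, vocab_size = 6)
sp  <- encode_trial(tr, cfg)
sp$harmonics
#>   k amplitude     phase
#> 1 1      0.25 0.8975979
#> 2 2      0.50 1.7951958
round(compute_variability(sp), 5)
#>          mean           std     variation autocorr_lag1       entropy
#>       0.75000       0.39528       0.15625       0.99832       0.50040
```

The first event occupies a quarter of the window (amplitude 0.25 at
frequency 1, phase $2\pi/7$ for ID 1), the second half of it; the trial fills
75 % of the window (`mean`), and its time budget is split 20/80 across the
two harmonics (`entropy` $= -0.2\log 0.2 - 0.8\log 0.8 = 0.50$).

A synthetic cohort with a strong planted link between neuroticism and
activity switching, analysed end to end:

```r
cc  <- cohort_config_aal(seed = 1, coupling = 20, base_rate = 1, item_noise = 0.2)
co  <- generate_cohort(cc)
enc <- encoding_config(window_min = 20, vocab_size = 6)
build_report(co$trials, co$scores, enc, modes = c("EN", "N"), seed = 1)
#>   period personality_mode     spectrum_feature  n  rate      r        p
#> 1   <NA>               EN         spectrum_raw 29 0.517 -0.173 0.369000
#> 2   <NA>                N         spectrum_raw 29 0.759 -0.610 0.000448
#> 3   <NA>               EN spectrum_variability 29 0.690  0.344 0.067300
#> 4   <NA>                N spectrum_variability 29 1.000  1.000 0.000000
```

The planted structure acts on the activity *count*, which the variability
features capture directly (rate 1.0 in the neuroticism-only mode for this
seed), while raw 200-point spectra dilute it across phases — the kind of
contrast the report is designed to expose. `run_pipeline()` /
`pipeline_config()` wrap the same chain with on-disk artifacts and a YAML
config; `inst/cli/habitspec.R` is a thin command-line front end with
`simulate`, `encode`, `features`, `score`, `cluster`, `associate` and
`run-all` subcommands.

See the vignette (`vignettes/behavioral-spectra.Rmd`) for the model, the
design decisions behind the encoding, and what the synthetic cohorts do and
do not demonstrate.

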