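# stnlfp

Analysis pipeline for intraoperative subthalamic nucleus (STN) local field
potentials recorded during the Simon conflict task, written for
neurophysiologists studying how STN subregions contribute to the control of
impulsive actions.

During deep-brain-stimulation surgery for Parkinson's disease, microelectrode
arrays traverse the STN, which makes it possible to record local field
potentials (LFPs) from the motor-connected **dorsal** and the
cognitive/limbic-connected **ventral** subregion while a patient performs a
conflict task. In the Simon task, a lateralized colour stimulus demands a
left- or right-hand response by colour; on *non-corresponding* (NC) trials
the stimulus side conflicts with the required response and the
location-driven impulse must be suppressed, slowing responses and producing
fast errors. Conflict control is associated with theta-band (4–7 Hz)
signalling, and movement inhibition with (low) beta-band (12–22 Hz)
signalling.

The package implements the full analysis chain:

* **Signal conditioning** — selection of the most variable of the three
  microelectrode channels over trial periods, three-channel common-average
  demeaning, anti-aliased decimation to 1000 Hz, linear detrending, a
  2nd-order Butterworth 1–100 Hz band-pass and a 59–61 Hz notch, all applied
  zero-phase.
* **Time–frequency analysis** — FFT-based complex Morlet decomposition with
  a linear cycle ramp (4 cycles at the lowest analyzed frequency to 12 at
  the highest); theta and low-beta band power; trial-wise baseline
  normalization, as decibels, `10·log10(P/P̄_base)`, and as z-scores against
  the subject's pooled band-specific baseline.
* **Trial QC** — a trial enters the analysis only if its response-locked
  window differs from its baseline window (two-sided paired *t* on the
  samplewise differences, α = 0.05); every exclusion is logged with a
  reason.
* **Response-locked binning** — the 380 ms before each correct button press,
  cut into four 95 ms bins; hemispheres are relabelled ipsilateral /
  contralateral to the responding hand per trial.
* **Behavior** — RT trimming (< 150 ms; > mean + 3 SD per condition),
  condition means, the Simon effects, delta plots with the final suppression
  slope `(d₄ − d₃)/(x₄ − x₃)`, conditional accuracy functions, and paired
  *t*-tests with Cohen's *d*.
* **Statistics** — a linear mixed model of log band power,
  `log P ~ subregion + correspondence + hemisphere + subregion:correspondence +
  correspondence:hemisphere + subregion:correspondence:hemisphere`
  with a random intercept per subject, a random correspondence slope, and a
  random time-bin slope nested within correspondence within subregion
  (Satterthwaite F tests; estimated marginal means; linear cell contrasts),
  plus Spearman correlations between per-subject baseline band power and
  the behavioral Simon effects.
* **Synthetic cohorts** — a generator that emulates the study's recordings
  (1/f background, common-mode noise and 60 Hz line, ongoing narrowband
  activity, response-locked theta/beta bursts with condition-dependent
  gains, subject-level random effects) and its behavior (ex-Gaussian RTs,
  impulse-capture race errors, 750–1250 ms intertrial intervals, 1000 ms
  deadline), so every stage is testable without patient data.

## Worked example

Simulate a small cohort, run the pipeline end to end, and look at the
conflict contrasts:

```r
library(stnlfp)

cfg <- run_config(
  sim = sim_config(n_subjects = 4, trials_per_block = 32,
                   blocks_per_depth = 1, fs_raw = 2000, seed = 7),
  tf  = tf_config(freqs = 2:30)
)
report <- run_pipeline(cfg, out_dir = "report")
report$contrasts
#> # A tibble: 8 × 7
#>   band  scope                   estimate     se        t     df       p
#>   <chr> <chr>                      <dbl>  <dbl>    <dbl>  <dbl>   <dbl>
#> 1 theta dorsal_NC_vs_Cs         0.377    0.0975  3.87      8.02 0.00475
#> 2 theta ventral_NC_vs_Cs       -0.0557   0.0975 -0.572     8.02 0.583
#> 3 theta ipsilateral_NC_vs_Cs   -0.000935 0.0975 -0.00959   8.02 0.993
#> 4 theta contralateral_NC_vs_Cs  0.322    0.0975  3.30      8.02 0.0108
#> 5 beta  dorsal_NC_vs_Cs         0.234    0.172   1.36    117.   0.177
#> 6 beta  ventral_NC_vs_Cs        0.283    0.172   1.64    117.   0.103
#> 7 beta  ipsilateral_NC_vs_Cs    0.503    0.172   2.93    117.   0.00412
#> 8 beta  contralateral_NC_vs_Cs  0.0131   0.172   0.0763  117.   0.939
```

Each row is a difference of estimated marginal means of log band power
between NC and Cs trials within a subregion (averaged over hemispheres) or
within a relative hemisphere (averaged over subregions). With the default
generator gains the dorsal theta conflict effect (row 1) and the
ipsilateral beta conflict effect (row 7) are positive and significant while
their ventral / contralateral counterparts are not — the dissociation the
analysis is designed to detect. `run_pipeline()` also writes
`behavior_summary.csv`, `theta_cells.csv`/`beta_cells.csv`, `contrasts.csv`,
`correlations.csv`, `powercells.csv`, `qc_log.csv` and `provenance.json`
into `out_dir`, byte-identically for identical configuration and seed.

The behavioral battery can be used on its own:

```r
co <- simulate_cohort(sim_config(n_subjects = 6, trials_per_block = 120,
                                 seed = 42), signals = FALSE)
bs <- behavior_summary(co$trials)
bs$effects
#> # A tibble: 2 × 11
#>   depth   simon_rt_ms  rt_t rt_df    rt_p  rt_d simon_acc_pct acc_t acc_df   acc_p
#>   <chr>         <dbl> <dbl> <dbl>   <dbl> <dbl>         <dbl> <dbl>  <dbl>   <dbl>
#> 1 dorsal         37.3  4.38     5 0.00718  1.79          9.40  2.81      5 3.76e-2
#> 2 ventral        41.8  5.61     5 0.00249  2.29         11.9   7.43      5 6.94e-4
```

`autoplot()` methods produce delta plots, conditional accuracy functions
and time–frequency maps; `tidy()`/`glance()` tidy the mixed-model fits.

The package ships the published reference result tables of the
intraoperative study it models (`reference_tables()`), and
`crossfoot_marginals()` verifies that the marginal means reported in that
study's results text are unweighted averages of its table cells:

```r
crossfoot_marginals()
#> # A tibble: 12 × 5
#>    band  scope          reported computed abs_diff
#>    <chr> <chr>             <dbl>    <dbl>    <dbl>
#>  1 theta dorsal             0.74    0.738  0.00250
#>  2 theta ventral            0.64    0.638  0.00250
#>  ...
```

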