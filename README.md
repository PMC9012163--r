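# penkin

Stroke-level handwriting kinematics for studying **motor anticipation** in
pen-tablet recordings, with a complete synthetic-cohort generator so every
stage runs without external data.

## The scientific problem

In fluent cursive writing, the stroke being produced already carries
information about the letter still to come. The classic probe writes the
bigrams *ll* and *ln* and measures the first *l*: a fluent writer lengthens
that letter's **downstroke** — in movement time and in path — when the next
letter is an *n* (which demands a change of size and rotation), but not when
the same *l* repeats. Populations with impaired motor planning, such as
patients with schizophrenia, are expected to lack this modulation while
writing larger (macrography) and less fluently (multi-peaked velocity
profiles). penkin is for researchers who record such tasks on digitising
tablets and want a tested, reproducible path from raw traces to the standard
inferential summary.

Per stroke the package measures the field's three classics:

- **Duration** (s): time between vertical-velocity reversals;
- **Trajectory** (cm): arc length of the pen path;
- **Dysfluency**: number of velocity peaks (a smooth stroke has exactly 1).

Subject-level cell means enter a random-intercept linear mixed model

> y[s,d,b] = mu + Group + Direction + Bigram + interactions + u[s] + e,
> u[s] ~ N(0, sigma²_subject), e ~ N(0, sigma²_residual),

fitted by profiled REML, with Type-III Wald F tests under sum-to-zero
coding, **Satterthwaite** denominator degrees of freedom, partial
eta-squared (eta²p = df1·F / (df1·F + df2)), Holm-adjusted `ll − ln`
contrasts within each group × direction, and a Spearman matrix against
clinical covariates (PANSS, SAS, CPZE, Purdue Pegboard, illness and
education years).

## Worked example

Simulate the default cohort (24 subjects per group, 10 trials per bigram,
200 Hz traces), extract first-letter features, and fit the duration model:

```r
library(penkin)

cfg     <- generator_config(seed = 42)
cohort  <- simulate_cohort(cfg)
cells   <- aggregate_cells(extract_features(cohort$manifest))
fit     <- fit_stroke_lmm(cells, "duration_s")

type3_f_tests(fit)
#>                     term      F df1 df2        p eta_p2
#> 1                  group   7.04   1  46 1.09e-02  0.133
#> 2              direction  71.03   1 138 4.15e-14  0.340
#> 3                 bigram 286.00   1 138 1.92e-35  0.675
#> ...
#> 7 group:direction:bigram 106.91   1 138 6.59e-19  0.437

bigram_contrasts(fit)
#>   group direction contrast estimate      se      t  df        p   p_holm
#> 1  CTRL        US  ll - ln -0.00385 0.00244  -1.58 138 1.17e-01 1.17e-01
#> 2  CTRL        DS  ll - ln -0.05683 0.00244 -23.28 138 1.24e-49 4.94e-49
#> 3   SCZ        US  ll - ln -0.00969 0.00244  -3.97 138 1.16e-04 2.32e-04
#> 4   SCZ        DS  ll - ln -0.01219 0.00244  -4.99 138 1.77e-06 5.30e-06
```

Reading the output: the Satterthwaite denominators land on the classical
split-plot values (46 between subjects, 138 within); the control downstroke
is ~57 ms longer before *n* than before a repeated *l* (the anticipation
effect, injected at 60 ms by the generator), while the control upstroke is
unmodulated. The three-way interaction carries the effect's signature. The
`trajectory_cm` and `n_peaks` models work identically, and
`plot_cell_means(cells, "duration_s")` draws the standard cell-mean figure
with standard-error bars. `run_pipeline(out_dir, config = cfg)` performs the
whole chain — simulate (or read a manifest of recorded trials), extract,
fit, correlate — and writes every table as commented CSV plus a run log.

Recorded data come in through a plain-text trace format (a `#` header with
`dialect`, `lpi`, `active_height_cm`, then `t,x,y,p` rows, in cm or raw
tablet counts) with a cohort manifest CSV; see `?read_pen_trace` and
`?read_manifest`.

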