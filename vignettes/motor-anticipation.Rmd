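---
title: "Stroke kinematics and motor anticipation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stroke kinematics and motor anticipation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

penkin analyses cursive handwriting recorded on a digitising tablet at the
level of individual strokes. Its scientific target is *motor anticipation*:
when a writer produces the first letter of a two-letter sequence (a bigram),
the kinematics of the current stroke carry the imprint of the letter still to
come. The canonical probe writes the bigrams *ll* and *ln* and compares the
first *l*'s descending stroke: a fluent writer lengthens that downstroke (in
time and in path) when the next letter is an *n*, which demands a change of
size and rotation, but not when the same *l* is simply repeated. A population
with impaired motor planning — the motivating case is schizophrenia — is
expected to lack this modulation, while showing generally larger strokes
(macrography) and more dysfluent (multi-peaked) velocity profiles.

This vignette documents the models, the tunable parameters, the synthetic
cohort generator, and the numerical choices, in that order. Everything
quantitative stated here is computed by the package's test suite or the
acceptance script; nothing is asserted from outside sources.

## From pen samples to stroke measures

A trial is a sequence of timestamped pen samples $(t, x, y, p)$: position in
cm (y up) and normalised pressure in $[0,1]$. The pipeline is:

1. **Resample** to a uniform grid (default 200 Hz) by linear interpolation.
   The tablet class targeted here reports positions at 5080 lines per inch;
   raw-count files are converted with $\mathrm{cm} = \mathrm{counts}/\mathrm{lpi}
   \times 2.54$ and flipped to y-up using the declared active-area height.
2. **Smooth** positions with a zero-phase (forward–backward) 4th-order
   Butterworth low-pass at 10 Hz. Zero-phase filtering preserves the timing
   of stroke boundaries; 10 Hz comfortably passes stroke-scale movement
   (strokes last 150–300 ms, so their fundamental sits near 3–7 Hz).
3. **Differentiate** by central differences (one-sided at the edges) to get
   $v_x, v_y$ and the tangential speed $\sqrt{v_x^2+v_y^2}$.
4. **Segment**. Pen-down runs are maximal stretches with $p$ above a
   pressure threshold (default 0.10). Within a run, stroke boundaries sit at
   reversals of $v_y$; a reversal only counts once $|v_y|$ has exceeded a
   hysteresis fraction (default 0.05) of the run's maximum $|v_y|$ on both
   sides, and the boundary lands on the sample where $|v_y|$ is smallest
   between the two flanks. Candidate strokes shorter than 30 ms are merged
   into their predecessor. Strokes alternate: upstroke (US, mean $v_y>0$),
   downstroke (DS, mean $v_y<0$).
5. **Measure** per stroke: duration (s) as the grid span between boundaries;
   trajectory (cm) as the polyline arc length of the smoothed path; and
   dysfluency as the number of interior speed maxima whose topographic
   prominence is at least 10% of the stroke's peak speed, with counted peaks
   at least 20 ms apart and plateaus counted once at their midpoint. Edge
   maxima are never counted: boundaries sit at velocity reversals where
   speed is locally low, so an endpoint maximum indicates segmentation
   slippage rather than dysfluency.

Both bigrams start with *l*, so the analysis unit — the first letter's US
and DS — is identified positionally as strokes 0 and 1 of the first pen-down
run. Trials whose first run has fewer than two strokes, or opens with a
downstroke, are flagged and excluded from aggregation rather than imputed;
exclusions are logged per cell.

### The dysfluency channel

Dysfluency events are faster than strokes. A secondary velocity pulse a few
tens of ms wide has spectral content around 20–40 Hz: the 10 Hz position
filter that is right for segmentation erases it entirely, while counting
peaks on unfiltered velocity amplifies tablet jitter (differentiation
multiplies noise amplitude by frequency) and produces spurious peaks. The
package therefore counts peaks on a *separate* velocity channel, obtained by
filtering the resampled positions at `dysfluency_cutoff` (default 35 Hz)
before differentiation. With the default prominence rule this choice counts
better than 99% of injected secondary pulses exactly while producing no
phantom peaks on pulse-free strokes, as verified in the test suite; at 25 Hz
and below detection collapses, and on raw velocity the phantom rate reaches
tens of percent. Segmentation, durations and path lengths always use the
10 Hz channel.

## The mixed model

Trials are averaged within each (subject, direction, bigram) cell — the
random unit of the design is the subject, and the printed denominator
degrees of freedom of the reference analyses (138 within, 46 between for 48
subjects) are the cell-mean values, not trial-level ones. Each measure is
fitted with the random-intercept linear mixed model

$$ y_{s,d,b} = \mu + \alpha_{g(s)} + \beta_d + \gamma_b + (\text{all
interactions}) + u_s + \varepsilon_{s,d,b},\qquad u_s \sim N(0,\sigma^2_s),
\ \varepsilon \sim N(0,\sigma^2_e), $$

with sum-to-zero coding for Group, Direction and Bigram. Estimation is
restricted maximum likelihood, profiled down to the variance ratio
$\lambda = \sigma^2_s/\sigma^2_e$: given $\lambda$, the GLS coefficients and
the profiled criterion are closed-form, and $\lambda$ is found by bounded
one-dimensional search with the $\lambda = 0$ boundary checked explicitly.
On small tables the optimum is verified against an exhaustive $\lambda$
grid, and the full fit (coefficients, variance components, REML
log-likelihood) is cross-checked against `lme4::lmer` in the test suite.

Inference follows the ANOVA-style reporting of the field:

- **Type-III Wald F tests** per term. In the $2\times2\times2$ design every
  term has one numerator df, so $F = t^2$ of the corresponding sum-coded
  coefficient. With balanced data Type I and Type III coincide, so the
  choice is safe and explicit.
- **Satterthwaite denominator df**: $\mathrm{df} = 2\,v^2 /
  \widehat{\mathrm{Var}}(v)$ with $v = c^\top (X^\top \Sigma^{-1} X)^{-1}
  c$, the variance of $v$ obtained by the delta method over
  $(\sigma^2_s, \sigma^2_e)$ using the inverse of the numerically
  differentiated REML information. On balanced cohorts this lands on the
  classical split-plot denominators (within terms near $n - S - 6$, the
  Group term near $S - 2$ for $S$ subjects), matching `lmerTest`.
- **Partial eta-squared** $\eta_p^2 = \mathrm{df}_1 F/(\mathrm{df}_1 F +
  \mathrm{df}_2)$ per term.
- **Bigram contrasts** `ll - ln` within each (group, direction): the
  anticipation probe itself. SEs come from the GLS coefficient covariance,
  df per contrast from the same Satterthwaite construction, and the
  four-contrast family is Holm-adjusted (reported alongside unadjusted
  p-values). Holm was chosen because it is assumption-free and conservative;
  the reference analyses do not state their adjustment.
- **Spearman matrix** between clinical covariates and per-subject mean
  kinematics, average ranks for ties, pairwise-complete, two-sided p from
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df.

## The synthetic cohort generator

No public dataset accompanies the design, so the generator is a first-class
module: it emits complete cohorts — pen traces plus clinical covariates —
whose effect structure matches the study design the package models,
calibrated so the *full pipeline* lands on the design's target descriptive
margins.

Cohort shape: 24 subjects per group, 2 bigrams, 10 trials per bigram
(repetition count is not stated in the reference design; 10 is a typical
graphomotor protocol and is configurable). Strokes are raised-cosine speed
pulses with a fixed 8° slant; trials are US/DS pairs for the first *l*
followed by a connected second letter (two nominal strokes for *l*, four for
*n*) that carries no effects but forces segmentation to isolate the first
letter; pen-up lead-in/out samples and Gaussian position jitter (0.002 cm)
complete the trace.

Per-cell nominal means were solved from the design's target *marginal*
means under balanced pooling and two-decimal rounding (the targets are
margins, never cells): US duration 0.195 s everywhere except SCZ/ln 0.205; DS 0.190
except CTRL/ln 0.250 and SCZ/ln 0.200; trajectory 0.625 cm for controls
except CTRL/ln/DS 0.725, and 0.840 for patients. The anticipation effect is
thus +0.060 s and +0.100 cm in the control ln downstroke only; patients get
a small direction-symmetric ln elevation (+0.010 s) so their contrasts stay
directionless, and uniformly larger strokes. Dysfluency: each first-letter
stroke receives $k \sim \mathrm{Poisson}(\lambda_{g,d})$ secondary pulses
($\lambda$ = 0.0325/0.1425 for CTRL US/DS, 0.4125/0.5225 for SCZ), so cell
mean peak counts are $1+\lambda$ and pool to SCZ 1.47, CTRL 1.09, DS 1.33,
US 1.22. Noise: subject intercepts (0.015 s, 0.05 cm), trial noise (0.030 s,
0.08 cm).

Three calibration details matter and are deliberate design choices:

- **Pulse feasibility.** Secondary pulses are 0.20 stroke-durations wide
  with centres at least 0.25 durations from each other and from the primary
  peak; at most two fit, so Poisson draws are capped at two and the
  generator solves a compensated rate $\lambda'$ with
  $E[\min(\mathrm{Pois}(\lambda'), 2)] = \lambda$, keeping cell means exact.
  The pulse amplitude (0.70 of the primary peak) and width were set, via an
  explicit signal-to-noise analysis, to the smallest values that the default
  detector counts exactly (no misses, no phantoms) under the default jitter;
  weaker or narrower pulses fall below the prominence floor once any
  realistic filtering is applied.
- **Path self-calibration.** Zero-phase smoothing replaces the zero-speed
  cusp at each stroke reversal with a rounded arc, lengthening the measured
  path by roughly 0.006–0.013 cm per stroke depending on stroke speed. The
  generator measures this deterministic bias per cell at configuration time
  (on noiseless plus fixed-seed noisy replicates) and subtracts it from
  emitted paths, so configured trajectory means are what the pipeline
  actually measures.
- **Clinical covariates.** Each variable is drawn from a truncated normal
  at its target mean and SD (PANSS subscales bounded at their scale
  minima 7/7/16, the rest at 0). Truncation shifts a naive mean upward —
  severely so for scales like SAS (3.21, SD 5.09, bound 0) — so the
  generator solves the location parameter such that the *realised* mean
  equals the target. The dominant-hand Purdue score is coupled to
  each patient's mean stroke trajectory by a Gaussian copula at Spearman
  $\rho = -0.5$ (worse dexterity, longer strokes); the Gaussian correlation
  uses the exact conversion $\rho_g = 2\sin(\pi\rho_s/6)$.

What the generator does *not* emulate: letter shapes (strokes are slanted
speed pulses, not glyphs), pressure dynamics, pen tilt, left-handedness,
macrography subtypes, or realistic between-measure correlations beyond the
Purdue–trajectory link. Passing tests therefore certify the measurement and
inference chain under a faithful effect structure, not realism of the
trajectories themselves.

## Numerical choices and degenerate inputs

- Stroke durations are grid quantities; boundary refinement below one
  sample period (5 ms at 200 Hz) is treated as spurious.
- The REML information is differentiated numerically with relative steps of
  $10^{-2}$ per variance component: the criterion's own numerical noise
  floor dominates smaller steps, and the truncation error at $10^{-2}$ is
  ~$10^{-4}$ relative (verified against the closed-form balanced-case
  information). Steps respect the $\theta \ge 0$ boundary; a singular
  information matrix is reported as an error, never silently replaced.
- Satterthwaite df are clamped to $[1, n-p]$.
- A monotone pen-down run yields a single stroke, not an error; a trace
  with no pen-down samples is an error.
- Peak-count ties on plateaus resolve to the plateau midpoint; when two
  peaks violate the separation rule the higher one wins, with sample index
  as the deterministic tie-break.
- Constant responses collapse both variance components to ~0 and are fitted
  without error.

## Known limitations

- The statistical layer supports two-level factors (1-df terms) only — the
  design it serves is strictly $2\times2\times2$. Multi-df Satterthwaite
  would need the eigenvalue construction.
- The SCZ ln elevation (+0.010 s) is detectable at the generator's default
  noise scales: with trial noise 0.030 s averaged over 10 trials the
  within-subject contrast SE is ~0.0027 s, giving the patient contrasts
  $|t| \approx 4$–$6$. A cohort calibrated this tightly is far more
  powerful than the reference study (whose $t \approx 3.3$ for a 0.060 s
  effect implies ~6× more cell-level residual), so "patients show no
  significant modulation" does not replicate under these defaults even
  though the patient effect is an order of magnitude smaller than the
  control one. The test suite states this expectation honestly rather than
  inflating the noise to mask it.
- Dysfluency counts depend on the detector parameters; they are reported
  under the defaults above and are not comparable across parameter sets.

## Reproducing the study-level numbers

`scripts/acceptance.R --seed <s> --out <path>` recomputes the analytic
effect-size examples and runs five seeded default cohorts through the full
pipeline, writing the pooled margins as JSON. The test suite's
study-level blocks use 5 cohorts (calibration), 50 cohorts (power of the
anticipation pattern), and 200 reduced null cohorts (12 subjects/group,
anticipation disabled) — sizes chosen to estimate the relevant rates with
adequate precision while keeping a full run in the tens of minutes.
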