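---
title: "Measuring prediction efficiency in visual-world eye-tracking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring prediction efficiency in visual-world eye-tracking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

In the visual world paradigm (VWP), a listener views an array of pictures
while a spoken sentence unfolds, and their eye movements index how fast and
how strongly they predict upcoming words. `vwpred` implements the complete
analysis chain for a two-group VWP study of predictive sentence
comprehension in which each trial shows four pictures — a *target* (the
patient compatible with both the sentence's agent and its verb), an
*agent-related* distractor, an *action-related* distractor, and an
*unrelated* distractor — while a subject-verb-object sentence plays with
fixed landmarks: verb onset at 750 ms, patient onset at 1300 ms, sentence
offset at 2100 ms, analysis window 0–2500 ms.

Three questions drive the statistics:

1. *Incremental strategy*: after the verb, do fixations rise only for the
   target (staged elimination) or also for the verb-compatible but
   agent-incompatible action-related distractor (TRACE-like parallel
   activation)? Answered by cluster-based permutation analysis (CPA) of
   each condition against the unrelated distractor.
2. *Prediction efficiency*: how strongly and how fast does looking shift
   toward the target relative to the unrelated distractor? Answered by
   growth-curve analysis (GCA) of the log-gaze proportion ratio and by
   divergence point analysis (DPA) of target versus agent-related looking.
3. *Individual differences*: do the per-participant efficiency indices
   covary with autism symptom severity (CARS-2) and autistic traits
   (AQ-Child, five subscales with FDR control)?

## From raw gaze to the occupancy tensor

Raw data are 120-Hz binocular samples on a 1920×1080 screen viewed at
650 mm. `detect_fixations()` applies an I-VT (velocity-threshold) filter
in five ordered steps: linear interpolation of invalid gaps up to 75 ms
per eye; binocular averaging with single-eye fallback; classification of
samples with angular velocity at or below 30 °/s (computed over a 20-ms
window; both values configurable — the threshold is the conventional
I-VT default, which the study's instrumentation cites without printing a
number); merging of adjacent fixations at most 75 ms *and* 0.5° apart
(conjunctive, applied until idempotent); and removal of fixations shorter
than 100 ms. Degrees are converted to pixels with a flat-screen model
(pixel pitch ≈ 0.2766 mm from the 24-inch diagonal).

Fixation centroids are assigned to four 384×384-px AOIs with half-open
boundaries (left/top edge in, right/bottom edge out), and occupancy is
binary-coded into 50-ms bins: condition *c* gets a 1 in bin
*[50b, 50(b+1))* when any fixation labelled *c* overlaps the bin by more
than 0 ms. We read "received fixation within each time bin" as *any
positive overlap* — the more inclusive convention; `min_overlap_ms` allows
stricter variants. The resulting participant × trial × bin × condition
binary tensor is the common currency of every statistical stage.

## The statistical engines

**Log-gaze proportion ratio.** For occupancies $y_T$ and $y_U$ of target
and unrelated, the response is
$\log\left(\frac{y_T + 0.5}{y_U + 0.5}\right)$ (natural log). At trial
level the occupancies are binary, so the ratio takes values
$\{-\log 3, 0, \log 3\}$; the 0.5 offsets keep it defined everywhere and
make it exactly antisymmetric under swapping the two conditions. Trial
level is the default response for the GCA because the model includes a
trial random intercept; a participant-level variant (proportions before
the ratio) is provided since either aggregation is defensible.

**GCA.** `fit_growth_model()` fits, by REML,
`value ~ (ot1 + … + otk) * group + (1 | participant) + (1 | trial)`,
where `ot1…otk` are orthonormal polynomial contrasts over the 50 bin
centres (zero mean, unit norm, orthogonal to 1e−10) and the neurotypical
group is the reference level. Wald *t* statistics are reported with
residual-df *p*-values by default — effectively a *z*-test at these sizes,
recorded in the output; Satterthwaite df via `lmerTest` is available.
Order selection (`select_order()`) compares k = 1…5 by forward
likelihood-ratio tests between ML fits, each order entering together with
its group interaction; REML is used only for the final reported fit. A
singular fit is retried without the trial intercept and flagged.

**CPA.** Per bin, a two-sided paired *t*-test on participant-level
trial-averaged proportions (condition minus unrelated); clusters are
maximal runs of ≥ 2 adjacent supra-threshold bins with the same sign
(cluster-forming α = 0.05), summarized by Σt. The null distribution is
the maximal |Σt| per permutation over 1000 within-participant sign flips
— the exact scheme for a paired comparison, with the family-wise
max-statistic construction; each cluster's
$p = (1 + \#\{\text{perm max} \ge |\Sigma t|\})/(n_{perm}+1)$, so
*p* ≥ 1/(n+1) and zero *p*-values cannot occur. Bins with zero
within-pair variance are excluded from clustering with a warning.

**DPA.** Within 750–2500 ms, a one-sided paired *t*-test (target >
agent-related) per bin; the onset is the left edge of the first run of
≥ 4 consecutive significant bins (200 ms — the run length is our choice,
configurable and recorded in all outputs, since the method is cited
without one). `bootstrap_divergence()` resamples participants with
replacement within each group (1000 iterations), reports each group's
bootstrap-mean onset with a 95% percentile CI alongside the original-data
onset (the literature is ambiguous about which is "the" estimate, so both
are emitted), and summarizes the between-group difference per paired draw
with a proportion-based two-sided *p* (+1-corrected, capped at 1).
Iterations with an undefined onset are recorded as missing; above 10%
missing a prominent warning accompanies the results.

**Associations.** Pearson correlations with Fisher-z 95% CIs between each
index (log-ratio index = mean log-ratio over bins 0–25, i.e. [0, 1300);
individual divergence point = first sustained run of target > agent-related
in a participant's own curves, `NA` when absent — never a sentinel value)
and CARS (where collected), AQ total, and the five AQ subscales. The FDR
family is the five subscales within each group × index pair — the
narrowest reading of subscale-wise correction — with Benjamini–Hochberg
adjustment; the family id is recorded in every row. Undefined divergence
points are removed pairwise. Behavioral accuracy is modelled as
`correct ~ group + (1 | participant) + (1 | trial)` (logistic); complete
separation is flagged instead of silently estimated.

## The synthetic cohort generator

No recorded gaze ships with the package; `simulate_cohort()` generates
datasets with known ground truth so every stage is testable. The latent
process is a dwell-based categorical process over five states (four AOIs
plus an explicit off-AOI background that absorbs residual probability, as
in real VWP data) on the 50-ms grid. At each dwell boundary the next
state is drawn from time-varying redraw probabilities with two logistic
phases: an agent-based ramp (midpoint 650 ms) lifts the target and
agent-related conditions from a common exploratory start level, then a
verb-based ramp with midpoint `verb onset + latency` carries the target
to its asymptote while agent-related looking decays; the action-related
condition carries a transient Gaussian bump after verb onset — the
signature of TRACE-like parallel activation. Group means of the latency
(700 ms NT, 830 ms autistic) and target asymptote (0.55 vs 0.45) were
fixed once so that the emergent group divergence points, cluster
windows, and accuracy statistics land near the values the method is
meant to resolve; a participant's own latency deviation shifts the whole
cascade, making latency a single ground-truth efficiency parameter.

Dwells last a minimum of 3 bins (150 ms) plus a geometric tail (mean
300 ms). The minimum guarantees that, at zero measurement noise, every
latent dwell survives the 100-ms duration filter and the recovered
tensor equals the latent occupancy *exactly* — a property the test suite
asserts. The price is that the marginal per-bin occupancy is a
persistence-smoothed, slightly lagged version of the redraw curves;
`latent_marginal()` computes that marginal exactly by a forward recursion
over (state, dwell age), and Monte-Carlo tests compare against it rather
than against the raw ramps.

Gaze realization adds AR(1) drift jitter (SD 15 px, coefficient 0.95 —
white noise at 120 Hz would exceed any saccade threshold between every
pair of samples, which is why the noise must be temporally correlated),
independent 2-px per-eye noise, and Poisson blinks (0.2/s) with uniform
50–300 ms durations so that both the interpolation (≤ 75 ms) and
non-interpolation branches of the filter are exercised. Scores are linear
links: AQ and CARS are group-level means (89.5/48.6 and 35.6, CARS in the
autistic-like group only) plus coefficients times the participant's
centred latency and bias plus Gaussian noise; the five AQ subscales are
equal shares of the total plus noise, re-summed so subscales always add
up to the total. Accuracy uses conditional logits 4.27/4.95 with a
2.2-SD participant intercept, giving ~93.4%/95.9% marginal accuracy and a
group gap that is usually *not* significant at this sample size.

What the generator does **not** emulate: saccade kinematics (transitions
are instantaneous), smooth pursuit, calibration drift, track-loss
asymmetries between eyes, item-level semantic variability, and any
dependence of blink rate on group. Passing tests therefore demonstrate
the correctness and calibration of the *analysis machinery* under a
plausible generative model, not properties of any real population. Two
honest mismatches are documented rather than tuned away: with 24 binary
trials per participant the reliability of the individual indices caps
attainable score correlations near |r| ≈ 0.25 (real data showed ~0.4),
and the individual divergence point is especially noisy.

## Numerical and design choices

- Bins are half-open `[t, t+50)`; bin *b* of the prediction window
  [0, 1300) is included only if it lies fully inside (bins 0–25; the bin
  starting at patient onset is excluded).
- Cluster start/end times are reported as member-bin centres.
- A fixation spans from its first sample to the next sample after its
  last (trial end: plus one rounded sample period), so a full-trial
  fixation has exactly the trial duration and boundary-touching
  fixations do not leak occupancy into adjacent bins.
- Timestamps are integer milliseconds from sentence onset; the 1000-ms
  preview is not part of the analysis timeline.
- The permutation and bootstrap engines sort participants internally, so
  all results are invariant to row order; every seed-taking function is
  deterministic under a fixed seed, and the pipeline derives per-stage
  seeds from one master seed (`seed * 8 + stage index`).
- Orchestration: the package is organised as an analysis workflow — the
  numbered drivers under `analysis/` run the stages over the functions in
  `R/`, and `run_pipeline()` provides the same chain as a single
  configurable call; there is no shell-level subcommand interface.

**Problem sizes in the test suite.** The statistical validation uses
scaled designs chosen to estimate each operating characteristic with
useful precision: 500 null cohorts of n = 20 for the cluster-level
false-positive rate; 100 cohorts at full scale (45/52) for
divergence-shift recovery and CI coverage; 100 model-generated datasets
of 16 + 16 participants × 12 trials for growth-model sign/magnitude
recovery and null calibration; exhaustive enumeration of all 32 sign
flips for the permutation oracle at n = 5.

## Known limitations

- The percentile-bootstrap CI for the divergence-point difference
  over-covers (~99% empirical at 95% nominal) because the run-criterion
  onset statistic is discrete on the 50-ms grid and non-smooth; the CI
  tracks the raw statistic's variability, which exceeds that of the
  smoother bootstrap-mean estimator. Interpret DPA CIs as conservative.
- Residual-df *p*-values in the GCA are mildly anti-conservative for
  between-participant terms (measured group-term false-positive rate
  ≈ 7% at nominal 5%); use `df_method = "satterthwaite"` when exact
  calibration of those terms matters.
- The I-VT filter trims roughly one or two samples at each dwell
  boundary (velocity-window edge effects), so latent dwells of exactly
  100 ms would be lost; the generator's 150-ms minimum dwell sidesteps
  this, real 100–130 ms fixations would not.
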