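---
title: "Models and methods behind pupilhab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pupilhab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pupilhab` analyses tonic arousal during the Sentence-final Word
Identification and Recall (SWIR) test: 28 blocks of 7 sentences presented
in 16-talker babble at an individualised signal-to-noise ratio, with pupil
diameter recorded at 1,200 Hz. This vignette explains the models and
procedures the package implements, the choices that were genuinely open,
and what the synthetic-data tests do and do not establish.

## The measurement model

The quantity of interest is the **pupil baseline** of a block: the mean of
the seven **sentence baselines**, each the mean pupil diameter over the
half-open 1 s window immediately before a sentence's onset
(`[onset − 1 s, onset)`; the onset sample itself is excluded, since the
window is defined as *prior to* the sentence). Averaging over the block's
seven sentences deliberately removes the within-block ramp produced by
accumulating items for later recall, leaving a per-block index of tonic
arousal. Units are millimetres of pupil diameter throughout; an intercept
near 3.5 mm is a physiologically ordinary tonic diameter.

## Preprocessing

The cleaning chain runs in a fixed order: eye selection → blink detection →
margin removal → interpolation → sentence filter → participant filter.

* **Eye selection.** The right eye is analysed unless the left eye carries
  strictly more valid samples; an exact tie keeps the right eye (it is the
  stated default).
* **Blink detection.** A sample is a blink when its diameter falls strictly
  below `mean − 3·SD` of the 1,200-sample sliding window containing it,
  with mean and SD computed over the window's valid samples. The window is
  *centered* on the sample and clipped at the trace edges; alignment is not
  dictated by the protocol, and a centered window treats blink onsets and
  offsets symmetrically. Detection is single-pass: thresholds always come
  from the original validity mask. Two numerical points are deliberate:
  the strict inequality makes a perfectly constant trace blink-free (its
  window SD is zero), and a relative guard of 10⁻⁹ on the threshold keeps
  floating-point cancellation on long traces from ever flagging a sample —
  a real blink undercuts its threshold by orders of magnitude more.
* **A property worth knowing.** For a rectangular dip of depth Δ occupying
  a fraction *f* of the window, the dip samples sit `(1 − f)·Δ` below the
  window mean while the threshold sits `3·Δ·sqrt(f(1−f))` below it, so the
  rule detects the dip only when `f < 0.1` — independent of its depth.
  A lone 120-sample artifact inside a 1,200-sample window is exactly at
  this knife edge, and two blinks inside one window can mask each other by
  inflating the window SD. This is a property of the published rule, not of
  this implementation; the test fixtures therefore use dips comfortably
  below a tenth of the window, and the blink-injection tests assert
  detectability only for isolated artifacts.
* **Margins and interpolation.** Each detected run is extended by 77
  samples before and 181 after (the sample counts are authoritative; 64 ms
  and 151 ms are their rounded documentation), overlapping extensions are
  merged, and the union of tracker-invalid and blink-extended samples is
  replaced by linear interpolation between the nearest valid neighbours
  (nearest-value fill at the trace edges).
* **Validity filters.** Sentence validity is the percentage of valid
  samples over the epoch `[onset − 1 s, offset + 1 s)` — the baseline
  window through the end of the post-sentence background noise, covering
  every sample the analysis consumes. It is measured *after* margin
  expansion and *before* interpolation (interpolation "replaces" values and
  would trivially make every epoch complete). A sentence is discarded below
  60% (exactly 60% is retained); a participant is excluded above 15% of
  sentences missing (exactly 15% is retained). Both epochs and the window
  alignment are configurable, since neither is pinned by the protocol.

## The session timeline

Background noise starts 3 s before the first sentence of a block and 1 s
before the remaining six, and stops 1 s after each sentence. Between
sentences there is a 4 s silent response interval (2 s after the seventh),
then a 4 s retention interval, a beep, self-paced free recall, and a short
break. Sentence audio duration is not part of the protocol's printed
constants; the generator uses 1.8 s. The nominal recall duration (10 s) and
break (7.5 s, the midpoint of the permitted 5–10 s) only shape the
synthetic timeline.

## Adaptive SNR procedures

The staircase starts with target and noise both at 70 dB SPL (SNR 0 dB) and
moves only the target: −0.8 dB after a correct sentence repetition, +3.2 dB
after an incorrect one, doubled on the first five trials (the doubling is
unqualified, so it applies to both directions). The update is applied after
every response including the first, and "the resulting SNR" is the value
after the final update (a mean-of-last-k alternative is available). SNR
arithmetic is carried in integer tenths of a dB, so accumulated values are
exact. The number of trials is not stated by the protocol; the default is 20 and the
equilibrium property is length-robust.

The asymmetric steps make the procedure a weighted up-down rule with
equilibrium at `p = 3.2/(3.2 + 0.8) = 0.8`, i.e. 80% intelligibility. Two
regimes matter for testing it. With a *steep* listener the track oscillates
tightly around the 80% point and the final SNR is an unbiased estimate of
it — the equilibrium test therefore uses a logistic listener with slope
2 per dB. With a *shallow* (realistic) listener the stationary track is
wide and skewed upward, because upward excursions decay at only
0.8 dB/trial; the final-SNR estimate then sits several tenths of a dB above
the 80% point. That bias is a property of the procedure, not an
implementation artifact.

The four training lists that follow adjust the staircase result by 0, +1 or
+2 dB per list for 6–7, 4–5 and 0–3 correctly identified final words
respectively, applied sequentially. The simulated listener identifies
single words with the sentence psychometric shifted by `log(19/4)` on the
logit scale, which places word identification at 95% exactly where sentence
intelligibility is 80% — the correspondence the SWIR protocol itself relies
on.

## The statistical workflow

Block (1..28), RS score and SNR enter as continuous predictors centered at
their grand means — centered but **not** divided by their SDs. The
unscaled-centered reading is forced by the reference post-hoc arithmetic:
the two simple slopes (−0.19 and 0.01 mm/dB) equal
`b_SNR ± b_RSxSNR × 9.57` only if the group means of centered RS are on the
raw scale (±9.57 ≈ the half-normal mean 0.7979 × 11.99), and the tested
grid −5..7 matches the raw SNR range 2.60–13.4 minus its mean 6.65. A
`standardize` flag restores full standardisation for users who want it.

The maximal model has all fixed effects up to the three-way interaction and
a by-participant random intercept with random slopes for all three
predictors (unstructured covariance, REML). Since RS and SNR are constant
within participant, their random slopes are only weakly identified — they
can only express heteroscedasticity of the participant intercepts — and the
maximal fit is routinely singular, which is precisely why the workflow
reduces it. A fit is declared singular when any random-effect SD falls
below 10⁻⁶ of the outcome SD or any random-effect correlation reaches
|0.999|.

**Backward elimination** runs in two phases. Phase 1 (random): each random
slope is tested by a REML likelihood-ratio test against the model without
it (identical fixed structure); removing a slope from a q-term covariance
removes q parameters, which sets the reference χ² df. The slope with the
largest p ≥ 0.1 is dropped, iterating; while the current fit is singular
the worst slope is dropped regardless of its p, since a boundary fit
already demonstrates over-parameterisation. Phase 2 (fixed): among terms
not contained in any retained interaction, the largest Wald p ≥ 0.05 is
dropped, refitting after each removal. The elimination thresholds (0.1
random, 0.05 fixed) are the conventional defaults of the stepwise procedure
this follows; neither is stated by the protocol. Marginality is enforced
among fixed effects only — a random slope may outlive its fixed
counterpart, and the recall model's expected final form (fixed RS, random
Block slope, no fixed Block) is exactly such a case.

**Inference.** Fixed-effect p-values and confidence intervals are Wald z
(`estimate ± 1.96·SE`), consistent with χ² reporting; this is a deliberate
divergence from t-based small-sample inference, documented rather than
hidden. The Type II ANOVA uses the Wald-increment construction on the full
fit's fixed-effect covariance: for term T with higher-order relatives R,
`χ²(T) = Q(R ∪ T) − Q(R)` with `Q(S) = β_S' V_S⁻¹ β_S`. On an orthogonal
design this collapses to the marginal (Type III) χ² of each term; the test
suite pins both this identity and agreement with an independent Type II
implementation. An alternative — refitting without R and testing T there —
was considered and rejected: it changes the variance components between
hypotheses and disagrees with the standard construction whenever the
removed relative carries real signal.

**R² and collinearity.** Marginal and conditional R² follow the
variance-decomposition definition: `σ²_f` is the variance of the
fixed-effect linear predictor over the data, `σ²_r` the mean over
observations of `z' Σ z` (the random-design quadratic form), `σ²_e` the
residual variance; marginal = `σ²_f / (σ²_f + σ²_r + σ²_e)` and conditional
adds `σ²_r` to the numerator. Variance inflation factors are
`1/(1 − R²_j)` from regressing each fixed-design column on the others;
centered predictors and their products are nearly orthogonal, which is why
all VIFs stay near 1.

**Post hoc.** Participants are median-split on RS; scores strictly above
the median are "high", the median itself and below are "low", so an odd
sample puts the extra participant in the low group (21 participants split
11/10). The simple slope of SNR in group g is the exact linear contrast
`b_SNR + b_RSxSNR · m_g`, with `m_g` the group mean of centered RS and a
delta-method SE from the fixed-effect covariance; the slope difference is
`b_RSxSNR (m_high − m_low)` with a Wald z. Group contrasts across centered
SNR values s ∈ {−5..7} are `(b_RS + b_RSxSNR·s)(m_high − m_low)`, tested
per point without multiplicity adjustment — each point compares only two
groups.

## The synthetic generator

The generator is first-class, tested code, and its defaults *are* the study
conditions: fixed effects (3.48, −0.01, 0.01, −0.09, −0.01) on the centered
scale; RS ~ N(41.72, 11.99) clipped to [0, 100] (clipping, not truncation —
at these parameters a clip is a ~3-in-10,000 event); SNR ~ N(6.65, 3.08);
random-intercept SD 0.3 mm, Block random-slope SD 0.003 mm/block and
block-level residual SD 0.1 mm, which at n = 21 reproduce the printed
uncertainty of the Block coefficient to the displayed precision. Covariates
are centered at *sample* means during generation, matching what the fitting
stage does.

Trace-level simulation holds each block's true mean over the block, adds a
linear memory ramp per sentence index (0.02 mm/sentence by default; the
underlying phenomenon is only known to be increasing, linearity is this
package's choice) in segments so that the pre-sentence baseline window of
sentence k sits on level k, and adds white Gaussian measurement noise.
Blinks are Poisson-placed artifacts with a 20 ms linear dip to 10% of the
local diameter, a drawn plateau and a 20 ms recovery — morphology chosen
for detectability, not biophysical fidelity. A `response_only` placement
mode confines blinks (including their downstream removal margins) to the
silent response intervals, yielding the clean-baselines fixture in which
every sentence keeps 100% validity.

Recall is Binomial(7, p) per block with
`logit(p) = g0 + g_RS·RS_c + u0 + (g_Block + u_Block)·Block_c`. The mean
structure has no Block trend by default (performance is stable over the
session); the by-participant intercept SD (0.5) and Block-slope SD (0.02,
logit scale) give the between-participant spread and the individual
time-trends a realistic recall record shows — with g_RS = 0.02 the implied
RS effect at n = 21 has a Wald z near 2.2, matching the magnitude of the
published behavioural effect. Setting both heterogeneity SDs to zero
recovers the pure RS-driven binomial generator.

What the synthetic tests establish: that the pipeline arithmetic is exact
(noiseless identities hold to machine precision), that the estimator
recovers the generating coefficients at n = 500 within tight tolerances,
and that the elimination procedure retains the generating structure with
high probability at n = 100 while pruning null terms at the nominal rate.
What they do not establish: robustness to real eye-tracker pathologies the
generator does not emulate (gaze-dependent foreshortening, slow drift,
partial occlusions, non-Gaussian noise), or the adequacy of the Gaussian
identity link for bounded recall percentages.

## Problem sizes and numerical choices

The recovery simulation uses 500 participants × 28 blocks (the scale at
which coefficient tolerances of ±0.005–0.05 are several sampling SDs wide);
the elimination study uses 100 replicates of 100 participants; trace-level
identity tests use 1–2 participants × 2–3 blocks at the full 1,200 Hz
rate. Mixed models are fitted with derivative-free convergence checks
disabled (`calc.derivs = FALSE`) — the finite-difference Hessian is pure
post-fit diagnostics and dominates runtime for the 4-term random structure —
and singularity is assessed by the package's own criterion rather than the
optimizer's. Rolling window statistics are computed from cumulative sums of
globally centered values, which keeps the cancellation error of a
multi-million-sample trace far below the 10⁻⁹ detection guard.

## Known limitations

* Inference is asymptotic (Wald z); at n = 21 participants, t-based
  intervals would be a few percent wider. The package reports what the χ²
  workflow implies and documents the divergence.
* The sentence epoch for the validity rule and the window alignment for
  blink detection are configurable conventions; other choices shift
  sentence validity percentages slightly.
* The blink detector inherits the duty-cycle blind spot described above;
  artifacts longer than ~10% of the window can evade a single pass.
* Recall percentages are modelled with a Gaussian identity link, mirroring
  the reference workflow; a binomial GLMM would respect the outcome's
  support but would not be comparable to the reference analysis.
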