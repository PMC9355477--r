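# pupilhab

Pupil-baseline habituation analysis for speech-in-noise recall testing.

## The problem

Long auditory recall tests are cognitively demanding, and a listener's
physiological arousal — indexed by the *baseline* (pre-stimulus) pupil
diameter — typically declines as a session progresses. On its own that
decline is ambiguous: it can mean the listener is disengaging from the task,
or merely habituating to it. The behavioural record disambiguates the two:
if recall performance stays flat while the pupil baseline falls, the decline
reflects habituation, not disengagement.

`pupilhab` implements the complete measurement-to-model chain needed to ask
that question with the Sentence-final Word Identification and Recall (SWIR)
paradigm — 28 blocks of 7 sentences in 16-talker babble, with the last word
of each sentence repeated immediately and freely recalled at the end of the
block — recorded with a 1,200 Hz eye tracker. It is aimed at hearing
scientists and psychophysiologists who need a tested, reproducible version
of this pipeline, including a synthetic-data generator so that every stage
can be validated without access to raw laboratory recordings.

## What it computes

**Preprocessing** (`run_preprocess()`): analysis-eye selection (right unless
the left eye has more valid samples), blink detection by a 1 s
(1,200-sample) sliding window — a sample is a blink when it falls more than
3 SDs below the window mean — removal of 77 samples (64 ms) before and 181
samples (151 ms) after each blink, linear interpolation of the gaps, then
two validity filters: sentences with less than 60% valid data are discarded,
and participants with more than 15% of sentences missing are excluded.

**Baselines** (`sentence_baseline()`, `block_pupil_baseline()`): the
sentence baseline is the mean pupil diameter over the 1 s before sentence
onset; the *pupil baseline* of a block averages its seven sentence
baselines, washing out the within-block memory-load ramp. Recall is scored
per block as the percentage of the seven repeated words recalled, order-free
(`recall_score()`).

**Adaptive SNR procedures** (`hint_staircase()`, `swir_training_adjust()`):
a weighted up-down staircase (−0.8 dB on a correct sentence repetition,
+3.2 dB on an incorrect one, doubled steps on the first five trials) whose
asymmetric steps target p = 3.2/(3.2+0.8) = 80% intelligibility, followed by
four training lists that nudge the SNR up by 0/1/2 dB depending on how many
final words were identified.

**Mixed-model workflow** (`analyze_blocks()` and its parts): with centered
continuous predictors Block (1..28), Reading Span score (RS, % correct, a
working-memory measure) and individual SNR (dB), the maximal model is

```
outcome ~ Block_c * RS_c * SNR_c + (1 + Block_c + RS_c + SNR_c | participant)
```

fitted by REML (lme4). Backward elimination prunes the random structure
first (REML likelihood-ratio tests, α = 0.1), then non-significant fixed
effects (Wald tests, α = 0.05, respecting marginality). The reduced model is
summarised with Type II Wald χ² tests, Nakagawa marginal/conditional R²,
and variance inflation factors. Post-hoc, participants are median-split on
RS and the conditional SNR slope is evaluated at each group's mean centered
RS (`simple_slopes()`), with predicted group differences tested across
centered SNR values −5..7 (`snr_grid_contrasts()`).

**Synthetic sessions** (`generator_config()`, `simulate_block_data()`,
`simulate_session()`): generators whose defaults encode the study
conditions — fixed effects (3.48, −0.01, 0.01, −0.09, −0.01) on the
centered scale, RS ~ N(41.72, 11.99) clipped to [0, 100], SNR ~
N(6.65, 3.08), by-participant random intercept and Block slope, binomial
recall driven by RS, blink artifacts, and a logistic listener for staircase
simulation. Every dataset ships its ground truth for recovery testing.

## Worked example

```r
library(pupilhab)

# simulate a study at the reference scale: 21 hearing-aid users, 28 blocks
sim <- simulate_block_data(generator_config(), seed = 2026)
head(sim$blocks, 3)
#>   participant block pupil_baseline_mm n_sentences_used recall_pct
#> 1           1     1          3.911611                7   42.85714
#> 2           2     1          3.872097                7   85.71429
#> 3           3     1          3.116128                7   28.57143

# full workflow: centering, maximal model, backward elimination, post hoc
res <- analyze_blocks(sim$blocks, sim$participants,
                      outcome = "pupil_baseline_mm")
res$fit
#> <swir_lmm: pupil_baseline_mm ~ block_c + rs_c + snr_c + rs_c:snr_c |
#>            random: intercept + block_c + rs_c>
#>   588 obs, 21 participants, REML
#>   estimate ci_lower ci_upper      p
#> 1   3.3881   3.2459   3.5303 0.0000
#> 2  -0.0106  -0.0122  -0.0089 0.0000
#> 3   0.0080  -0.0102   0.0262 0.3906
#> 4  -0.0770  -0.1281  -0.0260 0.0031
#> 5  -0.0144  -0.0200  -0.0088 0.0000

res$anova
#>         term      chisq df            p
#> 1    block_c 158.258996  1 2.716748e-36
#> 2       rs_c   4.090075  1 4.313573e-02
#> 3      snr_c 118.151620  1 1.606279e-27
#> 4 rs_c:snr_c  25.134174  1 5.347671e-07

res$slopes
#> Simple slopes of centered SNR by WM group:
#>   group m_rs_c   slope     se ci_lower ci_upper
#> 1   low -7.647  0.0331 0.0453  -0.0556   0.1218
#> 2  high  8.412 -0.1982 0.0169  -0.2313  -0.1651
#> difference (high - low): -0.2313, z = -5.01, p = 0.0000
```

Reading the output: the pupil baseline shrinks by about 0.011 mm per block
(habituation over the session), and the negative RS × SNR interaction means
the SNR slope is steep and negative for high-working-memory listeners
(−0.20 mm/dB here) but flat for low-working-memory listeners — high-WM
participants show elevated tonic arousal specifically at low SNRs. In this
n = 21 replicate the elimination also kept an RS random slope; at this
sample size the selected random structure varies from replicate to
replicate, which is exactly why the package ships recovery simulations at
larger n.

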