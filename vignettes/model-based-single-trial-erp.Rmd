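---
title: "Model-based single-trial ERP analysis of feedback learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based single-trial ERP analysis of feedback learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialpe)
```

## The analysis problem

In probabilistic feedback learning, people choose between stimuli with
unknown reward probabilities and gradually learn which options pay off.
Reinforcement-learning (RL) theory formalises this with per-stimulus
values $Q$ updated by prediction errors (PEs) — the difference between
obtained and expected outcome. Feedback-locked EEG components carry
signatures of this computation: the FRN/RewP (a frontocentral
deflection around 200–350 ms) and the P300 (300–500 ms) are both
modulated by how surprising an outcome is. `trialpe` implements the
full analysis chain that connects the two levels on a *single-trial*
basis: fit RL models to choice sequences, extract a trial-by-trial
unsigned PE, quantify single-trial component amplitudes from epoched
EEG, and relate amplitude to feedback valence, feedback timing
(immediate vs delayed) and the unsigned PE with crossed-random-effects
linear mixed models (LMMs), resolved by simple slopes.

Because participant-level EEG of this kind is typically not shareable,
the package ships a first-class synthetic-data module that generates
task designs, model-driven choice behaviour, single-trial amplitudes
with a known mixed-model structure, and noisy epochs with ground-truth
artifacts. Every downstream stage can therefore be validated against
known truth.

## The task and its simulation

The task pairs two of five stimuli per trial; the stimuli carry reward
probabilities 0, .2, .4, .6 and .8. A session has 3 blocks of 100
trials; each of the 10 unordered pairs appears 10 times per block with
left/right placement counterbalanced (5/5), and each participant
performs the task once with immediate (1 s) and once with delayed
(7 s) feedback. `generate_task_design()` reproduces exactly this
structure (other balanced sizes are allowed; with an odd number of
presentations per pair the sides are balanced to within one trial).
The feedback delay has no computational consequence for the simulated
agent, so it is carried as a label. Monetary magnitudes are metadata;
the models see binary reward $r_t \in \{0, 1\}$.

Rewards are drawn per choice (Bernoulli) by default. Whether the
original experiment pre-scheduled exact reward proportions is not
knowable from the outside; an `exact_proportion` mode schedules
per-stimulus outcome urns in cycles of five (the finest granularity
consistent with probabilities in steps of 0.2) for tests that need
deterministic proportions.

## The three learning models

All models start every stimulus value at $Q = 0.5$ and choose by
softmax with exploration parameter $\beta$:

$$p_{c,t} = \frac{e^{Q_{c,t}\beta}}{e^{Q_{c,t}\beta} + e^{Q_{u,t}\beta}}.$$

* **M1** — one learning rate: $Q_{c,t+1} = Q_{c,t} + \alpha\,\delta_{c,t}$
  with $\delta_{c,t} = r_t - Q_{c,t}$.
* **M2** — choice-confirmation bias: $\alpha_{con}$ applies after
  reward, $\alpha_{dis}$ after punishment.
* **M3** — M2 plus counterfactual updating of the unchosen stimulus
  with $\delta_{u,t} = (1 - r_t) - Q_{u,t}$, using the
  valence-selected rate.

Because each update is a convex combination of a value in $[0,1]$ and
an outcome in $\{0,1\}$, values remain in $[0,1]$; this is tested as a
property. Negative log-likelihoods sum $-\log p_{c,t}$ over trials
with probabilities floored at $10^{-12}$ so degenerate parameter
vectors stay finite.

Fitting uses bounded L-BFGS-B from 50 random starts, with start values
uniform on $[0,1]$ for *all* free parameters (the published procedure
states this interval literally, including for $\beta$ whose bound is
$[0,100]$; `beta_start_max` widens the start range if desired).
Learning rates are bounded in $[0,1]$, $\beta$ in $[0,100]$. The
forward pass is compiled (Rcpp), which also makes a dense
grid-search oracle cheap: the test suite verifies that the multi-start
optimum never exceeds the minimum over a $101 \times 101 \times 51$
parameter grid by more than $10^{-3}$. If the fitted learning rates
collapse to zero the likelihood is flat in $\beta$, and the fit flags
$\beta$ as unidentified.

Model comparison averages $-LL$ and $BIC = k\ln n + 2(-LL)$ across
sessions (one fit per participant × timing condition) and selects the
lowest mean BIC, ties going to fewer parameters. The published
comparison table for this paradigm uses an aggregation that cannot be
reconstructed from its printed values, so the package documents its
convention and validates selection behaviour by model recovery
instead: cohorts simulated from M3 select M3, cohorts from M1 prefer
M1.

For the ERP analyses the *unsigned* PE $|\delta_{c,t}|$ is used, since
the signed PE is confounded with feedback valence; PE–valence
interactions then test whether surprise effects differ between rewards
and punishments.

## Synthetic amplitudes and epochs

`generate_amplitude_table()` draws single-trial amplitudes from the
same model family the analysis fits: fixed effects for Valence,
Timing, |PE| (and Frontality for P300-style tables) with all
interactions, by-participant random intercept and slopes
(independent normals), a by-electrode random intercept, and Gaussian
residual noise. The factor coding is fixed throughout the package:
negative feedback = +1, delayed = +1, parietal = +1. The linear
predictor uses the grand-mean-centred |PE| — the same covariate the
analysis model sees — so generator coefficients and fitted
coefficients live on an identical scale; the output table keeps
`pe_abs` on its raw scale.

The default fixed effects of `frn_gen_params()` and
`p300_gen_params()` are the published single-trial estimates for the
two components (FRN/RewP: valence −0.38, timing −1.01, |PE| 0.94,
valence×timing 0.20, timing×PE −0.57, valence×PE −0.77, three-way
−0.07 µV; P300 analogously). Random-effect and residual SDs are not
published; the defaults (participant intercept 1.5 µV, slopes 0.4 µV,
electrode intercept 0.3 µV, residual 8 µV) are chosen once as typical
single-trial feedback-ERP magnitudes: residual noise far above the
fixed effects, between-participant variation comparable to the larger
coefficients, and a deliberately small electrode variance (the five
cluster electrodes are close together).

`generate_epochs()` embeds tabulated amplitudes into −200..+800 ms
epochs as Gaussian bumps (FRN-window component centred at 300 ms, SD
40 ms; P300 at 380 ms, SD 60 ms) plus white noise. The bumps overlap
in time, so per-trial component scales are obtained by solving the
2×2 linear system that makes the mean voltage in *each* component's
±30 ms window equal its target amplitude exactly — windowed-mean
extraction is then unbiased by construction, and the end-to-end test
demands agreement to $10^{-6}$ µV on noiseless data.

**Sampling rate.** The default is 500 Hz. This is a deliberate choice:
with the standard rejection thresholds, an isolated voltage-step
artifact (> 70 µV/ms) at 250 Hz would need an adjacent-sample jump of
more than 280 µV, which necessarily also violates the 200 µV swing
and ±150 µV amplitude criteria; at 500 Hz a 168 µV jump violates the
step criterion alone. One-violation-per-trial injection — a step, a
slow > 150 µV excursion, a flatline, and a > 200 µV/100 ms swing,
cycling — is what makes criterion attribution testable against the
ground-truth log. Artifacts are overlaid on the ongoing signal (the
flatline replaces it), because an artifact trace with constant
segments would spuriously co-trigger the minimum-activity criterion.

## ERP quantification

The quantification chain mirrors standard difference-wave practice:

1. **Baseline correction** over −200..0 ms (idempotent).
2. **Zero-phase filtering**: second-order Butterworth high-pass
   (0.1 Hz) and low-pass (30 Hz) plus a 50 Hz band-stop, each applied
   forward–backward; the epoch mean is removed first so DC maps to
   zero exactly.
3. **Artifact rejection** per trial across the electrodes under
   analysis: step > 70 µV/ms between adjacent samples (sampling-rate
   aware), swing > 200 µV in any sliding 100 ms window, any sample
   outside ±150 µV, and peak-to-peak range < 0.1 µV in any 100 ms
   window. "Activity" is interpreted as peak-to-peak range — the
   published criterion names only a threshold, not a definition.
   Rejection is monotone in every threshold (tested). The original
   procedure interleaved rejection with an ocular-correction step that
   requires EOG channels; without ocular correction in scope the
   package applies a single post-baseline pass.
4. **Peak detection**: the FRN/RewP window centre is the largest
   *local* negative peak (strictly below both neighbours; ties go to
   the earliest latency) of the punishment-minus-reward difference
   wave between 180 and 350 ms, separately per timing condition; the
   P300 centre is the largest local maximum of the valence- and
   cluster-pooled average between 300 and 500 ms. If a window contains
   no local extremum the windowed extremum is used and flagged with a
   warning.
5. **Single-trial amplitudes**: mean voltage per retained trial and
   electrode over the ±30 ms window around the detected peak.
   Time-to-sample mapping is nearest-sample with half-open
   `[start, end)` windows, so windows are bit-reproducible.

## Mixed-effects analysis

`encode_predictors()` effect-codes the two-level factors to −1/+1
(map recorded; decoding round-trips) and centres |PE| on its grand
mean while preserving the range. The maximal model follows the
published specification:

```
amplitude ~ valence * timing * pe +
  (valence * timing * pe | participant) + (1 | electrode)
```

`fit_erp_lmm()` estimates Gaussian LMMs with crossed participant and
electrode random effects via lme4, REML for final inference and ML
for likelihood-ratio comparisons, with Satterthwaite degrees of
freedom via lmerTest (the df method is recorded; if Satterthwaite
fails, residual df are used and flagged). Singular fits are flagged,
not fatal.

`select_parsimonious()` reimplements the two-stage stepwise
procedure: terms are added to an empty model in order of their
likelihood-ratio contribution (ML fits, $\chi^2$ with $\alpha =
0.05$, marginality respected: an interaction only becomes eligible
once its components are in; a random slope once its fixed term and
the group's intercept are in), then random terms are backward-
eliminated when their removal does not significantly change the
likelihood. Random slopes are expressed as independent
(uncorrelated) variance components, so each slope is a single
one-degree-of-freedom candidate; this keeps the candidate space
well-defined and the fits stable at the package's simulation scales,
at the cost of not modelling slope correlations.

`simple_slopes()` evaluates the conditional slope of a focal variable
at ±1 moderator levels as the derivative of the fixed-effect
predictor, with variables outside the moderator set averaged out at 0
(their coded mean), Wald z tests and Bonferroni correction. With the
published FRN fixed effects (PE 0.94, valence×PE −0.77, timing×PE
−0.57) this reproduces the printed slopes analytically: 1.71 for
positive and 0.17 for negative feedback, 1.51 for immediate feedback.
Published reports round such slopes from unrounded estimates (a
printed 0.34 can coexist with printed coefficients summing to 0.37),
so the package asserts the slope identity only on its own fits.

`power_simulation()` regenerates amplitudes with the focal
coefficient set to a hypothesised value, refits, and counts
significant focal tests, returning the proportion with an exact
binomial CI. The published 76.00% post-hoc power estimate depends on
the original (non-public) data and is not a reproduction target; the
machinery is instead validated by type-I calibration — with the focal
effect at zero the "power" must match $\alpha$ within binomial
tolerance, which it does (5.0% at 200 simulations in the acceptance
run).

## Behavioural statistics

`score_accuracy()` marks a choice correct when the higher-probability
pair member was chosen. `rm_anova()` runs the Timing × Block
within-subject ANOVA through `car::Anova` with Mauchly sphericity
assessment and Greenhouse–Geisser corrected df (a two-level factor
has $\varepsilon = 1$ by construction); partial $\eta^2$ is computed
from effect and error sums of squares. `binomial_chance_test()`
screens participants against chance with a one-sided exact binomial
test at $p_0 = 0.5$. `wilcoxon_learning_rates()` implements the three
published contrasts on the dual learning rates with the drop-zeros
convention, exact p-values for up to 25 untied non-zero pairs and a
continuity-corrected normal approximation beyond, reporting
$r = Z/\sqrt{N}$. Where the published analysis is ambiguous about
which rate enters the timing contrast, the package compares the mean
of the two rates (and exposes the bias contrast
$\alpha_{con}-\alpha_{dis}$ separately); learning rates at the
boundary are kept as estimated, without trimming.

## Problem sizes, tolerances and what the tests show

The validation suite runs at scales chosen to exercise every claim on
a single CPU: parameter recovery uses 20 replicates of 300-trial
sessions ($\alpha_{con} = 0.3$, $\alpha_{dis} = 0.1$, $\beta = 5$;
median $|\hat\alpha_{con} - 0.3| < 0.1$ and the confirmation-bias
ordering recovered in ≥ 80% of replicates); model recovery uses 20
cohorts of 4 agents; LMM coefficient recovery uses 10 participants ×
5 electrodes × 300 trials × 100 replicates, asserting per-term mean
bias below 0.1 (about 3.5 Monte-Carlo standard errors given the
~0.3 µV replicate SDs induced by by-participant slopes at
$n = 10$) and ~95% CI coverage of at least 88%.

Passing these tests shows the pipeline is *internally* coherent: the
estimators recover the structures the generator builds in. The
generator deliberately omits features of real EEG — correlated pink
noise, ocular artifacts, volume-conducted component overlap beyond the
two modelled bumps, drifting impedances, reaction times — so the
results certify the statistical machinery, not biological claims about
any real dataset.

## A short worked example

```{r example, eval = FALSE}
library(trialpe)

result <- run_pipeline(pipeline_config(
  seed = 1, n_participants = 4, mode = "amplitude"))

result$comparison$table   # M1-M3 mean -LL and BIC; M3 selected
tidy(result$lmm)          # fixed effects with Satterthwaite df
simple_slopes(result$lmm, "pe", "valence")
plot_learning_curves(result$accuracy)
```
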