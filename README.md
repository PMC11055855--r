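# trialpe

Model-based single-trial ERP analysis of probabilistic feedback
learning, end to end and in R.

## What problem this solves, and for whom

Cognitive neuroscientists studying reward learning routinely want to
know whether feedback-locked EEG components — the FRN/RewP
(~200–350 ms, frontocentral) and the P300 (~300–500 ms) — track the
*prediction error* (PE) of a reinforcement-learning model rather than
just feedback valence. Answering that requires a chain of machinery
that usually lives in scattered scripts: simulate or load the
two-alternative probabilistic selection task (five stimuli with
0/20/40/60/80% reward probability, 3 blocks × 100 trials per timing
condition), fit competing Q-learning models to each participant's
choices, derive trial-level unsigned PEs from the winning model,
quantify single-trial component amplitudes from epoched EEG, and
relate amplitude to Valence × Timing × |PE| with crossed-random-effects
mixed models. `trialpe` packages that chain with a synthetic-data
module that gives every stage known ground truth.

## The models at the core

Stimulus values start at $Q = 0.5$ and choices follow a softmax,
$p_c = e^{Q_c\beta} / (e^{Q_c\beta} + e^{Q_u\beta})$. Three nested
learning rules are fitted by 50-start bounded maximum likelihood and
compared by mean BIC ($k\ln n + 2\,(-LL)$):

* **M1**: $Q_{c,t+1} = Q_{c,t} + \alpha\,(r_t - Q_{c,t})$, one rate;
* **M2**: separate $\alpha_{con}$ (after reward) and $\alpha_{dis}$
  (after punishment) — a choice-confirmation bias;
* **M3**: M2 plus counterfactual updating of the unchosen option,
  $Q_{u,t+1} = Q_{u,t} + \alpha\,((1-r_t) - Q_{u,t})$.

Downstream, single-trial amplitudes (windowed means around
difference-wave or pooled-average peaks) are analysed with

```
amplitude ~ valence * timing * pe +
  (valence * timing * pe | participant) + (1 | electrode)
```

after −1/+1 effect coding and PE centring, with stepwise term
selection, Satterthwaite degrees of freedom, Bonferroni-corrected
simple slopes, and simulation-based power.

## Worked example

```r
library(trialpe)

result <- run_pipeline(pipeline_config(
  seed = 1, n_participants = 4, mode = "amplitude"))

result$comparison
#> <model_comparison> selected: M3
#>   model     k mean_neg_ll mean_bic n_sessions
#> 1 M1        2        146.     304.          8
#> 2 M2        3        145.     306.          8
#> 3 M3        3        123.     264.          8
```

The cohort was simulated from the counterfactual model (M3,
$\alpha_{con} = 0.3$, $\alpha_{dis} = 0.1$, $\beta = 5$), and M3 wins
the BIC comparison across the 8 sessions (4 participants × 2 timing
conditions). The mixed model on generated amplitudes recovers the
structure the generator embeds (defaults are the published FRN/RewP
fixed effects):

```r
tidy(result$lmm)
#>   term              estimate std.error       df statistic  p.value
#> 1 (Intercept)         2.58      1.07       3.19    2.40   9.07e- 2
#> 2 valence            -0.0307    0.0806 11985.     -0.381  7.03e- 1
#> 3 timing             -0.732     0.0806 11985.     -9.08   1.26e-19
#> 4 pe                  0.747     0.290  11985.      2.58   9.92e- 3
#> 5 valence:timing      0.153     0.0806 11985.      1.90   5.76e- 2
#> 6 valence:pe         -0.933     0.290  11985.     -3.22   1.28e- 3
#> 7 timing:pe          -0.631     0.290  11985.     -2.18   2.93e- 2
#> 8 valence:timing:pe   0.0157    0.290  11985.      0.0541 9.57e- 1

simple_slopes(result$lmm, "pe", "valence")
#>   valence  slope std.error statistic  p.value
#> 1      -1  1.68      0.427     3.94  0.000164
#> 2       1 -0.186     0.392    -0.475 1
```

With negative feedback coded +1, the PE slope is large and reliable
for positive feedback (valence −1) and flat for negative feedback —
the PE × valence signature of a reward PE at this small simulation
scale. Analytically, the published FRN fixed effects reproduce the
published conditional slopes exactly:

```r
simple_slopes(c(pe = 0.94, "valence:pe" = -0.77), "pe", "valence")
#>   valence slope
#> 1      -1  1.71   # positive feedback
#> 2       1  0.17   # negative feedback
```

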