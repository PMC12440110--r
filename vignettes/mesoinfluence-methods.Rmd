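---
title: "Models and methods behind mesoinfluence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mesoinfluence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mesoinfluence` packages two analysis families that are usually studied
together in computational psychiatry — reinforcement-learning modeling of
bi-valent bandit behavior, and directed influence analysis of a
seed-centered brain network — together with a synthetic-cohort generator
that provides ground truth for both. This vignette explains the models,
the tunable parameters, the numerical choices, and what the synthetic
data can and cannot tell you about real data.

## The bandit task and Q-learning agents

The task is a two-armed probabilistic selection task with three
interleaved trial types (gain, loss, neutral; 30 trials each by default,
90 in total). Each trial type has a fixed stimulus pair; one member of
each pair is the high-probability arm. On gain trials the good arm pays
+1 with probability 0.8 (the other with 0.2); on loss trials the good arm
*avoids* a −1 outcome with probability 0.8; neutral trials always pay 0.
The magnitudes are configurable — the ±1/0 coding is the standard choice
for this family of tasks — and "correct" on loss trials means choosing
the loss-avoiding arm, which keeps learning curves comparable across
valences.

Agents learn action values by the delta rule

$$Q_t(s,a) = Q_{t-1}(s,a) + \alpha\,\big(r_t - Q_{t-1}(s,a)\big),$$

with all values initialized at zero, so the reward prediction error (RPE)
on the first encounter of a stimulus equals its outcome. Choices follow a
softmax with inverse temperature $\beta$:

$$p_t(a) = \frac{e^{\beta Q_t(a)}}{\sum_{a'} e^{\beta Q_t(a')}}.$$

Three model variants are implemented: model 1 has a single learning rate;
models 2 and 3 split it into $\alpha_G$ (gain and neutral trials) and
$\alpha_L$ (loss trials). Model 3 shares model 2's likelihood but gives
each clinical group its own set of group-level hyperparameters. Only the
chosen arm's value is updated. Neutral trials nominally use $\alpha_G$,
but with zero outcomes and zero initialization they contribute no updates
under the defaults.

The compliance filter excludes subjects whose correct-choice rate is
below 50% on gain **and** loss trials (the conjunctive reading; a
disjunctive switch is provided because the rule's plain-language form is
ambiguous) or who never responded.

## Hierarchical Bayesian estimation

Subject parameters live on unconstrained scales — learning rates through
a probit link, $\beta$ through a log link — with a non-centered hierarchy
$u_{s} = \mu + \sigma z_s$, $z_s \sim N(0,1)$. Priors are weakly
informative: $\mu \sim N(0,1)$ and $\sigma \sim \text{half-}N(0.5)$ on
the unconstrained scale, both exposed in `model_spec()` so alternative
values can be dropped in.

Sampling uses an adaptive Metropolis-within-Gibbs scheme implemented in
C++: componentwise random-walk updates of each subject's $z$ and of every
group-level location and log-scale, with proposal standard deviations
tuned toward a ~0.3–0.5 acceptance rate during warmup only (so the
post-warmup chain is a valid fixed-kernel Markov chain). Four chains of
1000 warmup + 1000 sampling iterations are the default; the light
configurations used in the test loops (2 × 500) were checked against the
defaults on pilot fits. Draws are deterministic given a seed. Convergence
is summarized by split-R-hat and an initial-positive-sequence effective
sample size per group-level parameter; a fit with `max_rhat` well above
1.05 should be rerun longer.

Model comparison uses WAIC computed from the per-trial pointwise
log-likelihood (trials are the exchangeable likelihood units):
`lppd = sum_t log mean_s exp(ll_st)`, `p_waic = sum_t var_s(ll_st)`,
`waic = -2(lppd - p_waic)`, with differences reported against the best
model together with `2 * sqrt(n * var)` standard errors of the pointwise
differences. No-response trials are dropped from the likelihood (they
contribute exactly zero) but kept in the records with a flag.

The posterior predictive check replays full sessions from thinned
posterior draws and overlays the observed correct-choice curve, by trial
position within type, on the central 95% predictive band. The
parameter-recovery harness draws true parameters from a deliberately wide
hierarchy (probit-scale SD 0.9, log-scale SD 0.5) — a recovery study
probes identifiability across the support, not one cohort's narrow range
— then refits and reports truth-estimate correlations, bias, CI coverage
and the correlation of estimation errors between $\alpha$ and $\beta$.

## Dependency network analysis

For each subject the node-by-node Pearson correlation matrix $C$ is
computed from the ROI time series. The partial correlation of nodes
$j,k$ given a third node $i$ is

$$PC(j,k \mid i) = \frac{C_{jk} - C_{ji}C_{ki}}
{\sqrt{(1-C_{ji}^2)(1-C_{ki}^2)}},$$

and the *correlation influence* of $i$ on the $j\!-\!k$ connection is the
Fisher-z drop $d(j,k\mid i) = \max\{0,\ \mathrm{atanh}(C_{jk}) -
\mathrm{atanh}(PC(j,k\mid i))\}$. The Fisher transform is applied to both
terms before differencing (a raw-difference variant is available via
`fisher = FALSE`); negative influences — suppression configurations — are
clamped to zero. Averaging over pairs gives the dependency matrix
$D_{ji} = \tfrac{1}{n-1}\sum_{R \notin \{i,j\}} d(j,R\mid i)$, from which
the **influencing** degree of a node ($\sum_N D_{Ni}$, the influence it
exerts) and its **influenced** degree ($\sum_N D_{iN}$) follow. Both
degree vectors always share the same total, which is a useful internal
check.

Three numerical conventions deserve a note. First, unit correlations are
replaced by 0.99 immediately before any Fisher transform (this is what
keeps the transform finite; reported correlation matrices keep their unit
diagonal, and diagonal terms never enter the sums). Second, the
degenerate self pair $R = j$ is excluded from the average while the
printed $1/(n-1)$ normalization is retained; a `normalization =
"n_minus_2"` switch averages over the terms actually summed. Group and
covariate contrasts are invariant to this constant. Third, degree
outliers are masked by a single, non-iterative 3-SD rule computed on the
full sample.

Group and covariate analyses of the degrees are ordinary least squares
with nuisance covariates (age, sex, medication, a preprocessing
covariate); the single-node analysis carries no multiple-comparison
correction, while the per-edge analyses behind the directed graph carry
Benjamini–Hochberg q-values over the tested edge family and draw edges at
uncorrected p < 0.05 with the FDR annotation attached.

## The synthetic cohort generator

Ground-truth data come from a structural VAR(1): every node has an AR(1)
self-decay (0.3 by default) and the hub's directed couplings act
*contemporaneously*, i.e. $x_t = A_0 x_t + A_1 x_{t-1} + \varepsilon_t$
with hub→target weights (0.4) and target→hub weights (0.05) in $A_0$, and
the reduced form $x_t = (I-A_0)^{-1}(A_1 x_{t-1} + \varepsilon_t)$ is
simulated after a discarded burn-in. The contemporaneous placement is
deliberate and load-bearing: zero-lag correlation methods cannot see an
influence confined to the previous timestep — under purely lagged
coupling each target correlates more with the other targets (all driven
by the hub's past) than with the hub itself, and the hub would rank
*last* in influencing degree, not first. At fMRI sampling rates,
node-to-node influence is effectively within-sample, so the
contemporaneous form is also the more realistic reading. Stationarity
(spectral radius of the reduced-form transition < 1) is enforced at
configuration time.

The MDD-like group receives an additive shift (0.1) to the outgoing hub
coupling, planting the group difference the influence analyses should
find. Covariates are drawn independently on their instruments' usual
scales except where an association is planted; planted effects are linear
in the standardized covariate and act on the hub coupling, and every
planted coefficient is stored in the cohort's ground truth, which
round-trips losslessly through the plain-text writers. Behavioral ground
truth follows the group-split hierarchy: gain learning rates center on
0.35 (HC) versus 0.20 (MDD) on the probability scale with probit-scale SD
0.4, loss learning on 0.30 for both groups, and β is log-normal around 5.
Default cohort sizes are 34 HC and 35 MDD.

What the generator does *not* emulate: hemodynamic convolution, 1/f and
physiological noise spectra, motion artifacts, scanner drift, or
missing-data patterns. A pipeline that passes every test here has been
shown to recover known signals from clean, correctly specified generative
families — not to be robust to fMRI's real nuisance structure.

## Study sizes used by the test loops

The recovery and comparison loops run at deliberately modest sizes chosen
as the smallest that give stable answers: parameter recovery and WAIC
model comparison use 30 subjects × 90 trials × 20 replicates with 2 × 500
(or 2 × 400) chains; the rank-sum power loop uses 50 replicate cohorts of
30 + 30 subjects fitted with the group-split model; the mixed-model power
loop uses 30 replicate cohorts of 35 + 35 subjects with a planted
gain-learning deficit calibrated in a pre-freeze pilot to ~95% power
(probability-scale gain-learning means 0.50 versus 0.05); hub recovery
uses 50 subjects × 1000 timepoints. Null-calibration loops use 150–400
replicates.

## Design choices where the design was open

- **Exclusion rule direction.** "Below 50% on gain and loss" is
  implemented conjunctively (both must be low), with `rule = "or"` as a
  switch; the conjunctive reading is the one under which a subject good
  at either valence is retained.
- **Group contrasts use the unpaired rank-sum test** (with exact
  enumeration under midranks for small samples); the paired signed-rank
  test is exposed separately for within-subject contrasts.
- **The learning-curve model is linear** on the binary outcome, exactly
  as the formula `correct ~ group * trial_type + trial + (1 | subject)`
  implies, with a logistic switch. Loss trials are the reference level,
  so a gain-specific deficit in the second group appears as a negative
  interaction.
- **Model 3 splits every hyperparameter by group** (locations and
  scales of both learning rates and β), the most direct reading of "two
  separate sets of group-level hyperparameters".
- **Subject estimates for group contrasts come from model 3.** A
  single-group hierarchy shrinks all subjects toward one common mean,
  attenuating exactly the contrast under study; the group-split hierarchy
  shrinks within groups and leaves the between-group signal intact, and
  it matches the cohort's generative structure.

## Known limitations

The Metropolis-within-Gibbs sampler mixes more slowly than gradient-based
samplers; very small effective sample sizes can occur for group-level
scales at small n, and the diagnostics table should be consulted before
interpreting a fit. WAIC standard errors are asymptotic in the number of
trials. The DEPNA influence measure is a descriptive zero-lag quantity:
it identifies which node's removal most changes the others'
correlations, which tracks — but is not the same thing as — causal
influence, and the package makes no causal claims beyond the planted
ground truth of its own simulations.
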