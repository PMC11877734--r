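---
title: "Models and methods in rwlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in rwlearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwlearn)
```

`rwlearn` implements the computational pipeline of a study comparing
probabilistic learning between autistic and non-autistic adults across
three tasks: generative simulators for the task designs, three
Rescorla-Wagner (RW) reinforcement-learning models with per-participant
and hierarchical Bayesian estimation, PSIS-LOO model comparison, and the
behavioural statistics used around them. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic-data machinery does and does not emulate.

## The three task designs

**Single-cue probabilistic learning.** Stimuli carry four binary
features; exactly one (the target) predicts which of two "art periods"
is shown as feedback. The deterministic condition is 100% predictive; the
probabilistic condition 75%. A session has 100 experimental trials, 50
per period, plus 8 interleaved catch trials (a displayed label to copy).
The 75% contingency is realised as a *fixed count* — exactly 75 of 100
trials congruent, split 37/38 between the periods at random — rather
than per-trial Bernoulli draws. The design description does not say
which scheme the original task used; the fixed count guarantees the
stated predictive strength in every generated session and gives tests an
exact target. The original art images vary continuously, so no two
stimuli repeat; with four abstract binary features that cannot hold
literally, and we instead sample the three non-target features i.i.d.
uniform per trial and give every trial its own stimulus identifier.

**Multi-cue probabilistic learning.** The 16 stimuli are the Cartesian
product of four binary cues; each carries a fixed probability of
receiving a "high" rating, from 0.100 to 0.900 (`build_multicue_stimuli()`).
Probabilities in [0.4, 0.6] define the *ambiguous* (weakly predictive)
condition, the rest the *unambiguous* condition. Ratings are drawn
per-trial: the stimulus is rated high when its probability exceeds a
uniform random number — this per-trial Bernoulli rule is stated by the
task description, so it is kept stochastic (unlike the single-cue
contingency). Sessions present the 16 stimuli as a set repeated eight
times (128 trials), blocked by set and shuffled within set, with 8
catch trials. Cue-to-design-column assignment is a permutation argument;
relabelling changes only the presentation bits, never the probability
map.

**Two-armed bandit (reinforcement learning task).** Twenty experimental
trials plus two catch trials. One option, chosen uniformly at random at
session start, is the rewarded one with probability 0.7 per trial,
independently and with no reversals. Outcomes are strictly
anti-correlated — exactly one option rewarded per trial — which is the
premise of the counterfactual model below.

In all tasks, catch trials never count towards the early/late phase
split: the first half of *experimental* trials is "early", the second
"late". All generators are bit-reproducible from their seed, and the
seed handling restores the caller's RNG state.

## The Rescorla-Wagner models

Rewards are coded $R \in \{+1, -1\}$ (rewarded / not rewarded) and all
option values start at 0, so values stay in $[-1, 1]$.

*Simple RW*: only the chosen option's value is updated,
$$\delta_t = R_t - V_t, \qquad V_{t+1} = V_t + \alpha\,\delta_t,$$
with learning rate $0 < \alpha < 1$.

*Positive/negative RW*: two learning rates; $\alpha^+$ scales
non-negative prediction errors (the $\delta = 0$ tie is deliberately
assigned to the $\alpha^+$ branch), $\alpha^-$ negative ones.

*Counterfactual RW*: both options update on every trial — the chosen one
with $R$, the unchosen one with the fictitious outcome $-R$:
$$V^c_{t+1} = V^c_t + \alpha (R_t - V^c_t), \qquad
  V^{nc}_{t+1} = V^{nc}_t + \alpha (-R_t - V^{nc}_t).$$
Because the bandit's outcomes are anti-correlated, the fictitious update
is exactly right, and with symmetric zero initialisation
$V^{nc}_t = -V^c_t$ holds for all $t$ (an exact invariant the tests
exploit).

**Choice rule.** The task description never prints its choice rule; we
use the convention of the modelling toolkit it names: a softmax on the
value difference,
$$p(a_t = 1) = \frac{1}{1 + e^{-\beta (V^{(1)}_t - V^{(2)}_t)}},$$
with inverse temperature $\beta \in [0, 10]$. $\beta = 0$ is
indifference; the upper bound matches the same convention. The
likelihood of a trial is accumulated *before* the value update of that
trial (predict, then learn). Catch trials and timed-out trials
contribute no likelihood term and trigger no update.

Because the original priors, chain counts and choice-rule constants are
not reported, absolute LOOIC values of the original fits are not
reproducible; model *ranking* and group-level parameter structure are
the quantities this package aims to reproduce.

## Estimation

**Maximum likelihood** (`fit_rw_mle()`): box-constrained L-BFGS-B over
$\alpha \in (10^{-4}, 1-10^{-4})$, $\beta \in [0, 10]$, from a fixed
midpoint start plus seeded random restarts (default 10). A fit is
flagged non-identifiable when it cannot beat the random-choice model by
a likelihood-ratio margin ($\chi^2_{2,0.95}/2 \approx 3$ nats) or lands
at $\beta \approx 0$; with 20-trial sessions this happens regularly and
is informative.

**Hierarchical Bayes** (`fit_rw_hier()`): one model per group.
Individual parameters are non-centred normal deviates on a latent scale
mapped through the standard-normal CDF: $\alpha = \Phi(\mu_\alpha +
\sigma_\alpha z)$, $\beta = 10\,\Phi(\mu_\beta + \sigma_\beta z)$.
Hyperpriors are weakly informative: $\mu \sim N(0,1)$,
$\sigma_\alpha \sim N^+(0, 0.2)$, $\sigma_\beta \sim N^+(0, 1)$ —
mirroring the conventions of the toolkit named by the study. Sampling is
MCMC via JAGS (rjags), defaults 4 chains, 1000 warmup, 1000 retained
draws, 500 adaptation steps, all seeded per chain for bit
reproducibility. Convergence is summarised by the split-chain statistic
(threshold 1.1; exceeding it warns but still returns results) and
effective sample sizes. A Gibbs/slice sampler has no divergent-transition
diagnostic, so that field is reported as `NA`. Pointwise log-likelihood
draws are computed in R from the posterior parameter draws with the
package's own likelihood recursion; reordering participants is
invariant in distribution but not bit-identical (the sampler consumes
randomness in participant order).

Group comparisons on learning rates use the per-participant *posterior
means* of the best-fitting model as t-test inputs; the original report
does not state its individual-level summary, and the posterior mean is
the conventional choice.

**PSIS-LOO** (`compute_loo()`): Pareto-smoothed importance sampling,
implemented in-package: per observation, the largest 20%/3√S of
importance ratios are replaced by quantiles of a generalized Pareto
distribution fitted with the Zhang–Stephens profile posterior-mean
estimator (shape regularised towards 0.5 with weight 10), weights
truncated at the raw maximum. `LOOIC = -2\,\mathrm{elpd}_{loo}`; lower
is better. The implementation agrees with an independent reference
(arviz) to ~1e-12 on test matrices; the test suite asserts agreement
within 0.1 elpd on a frozen fixture. Exact LOOIC ties in
`compare_models()` are broken by parsimony (fewer parameters, then
declaration order), so an all-tied comparison returns the simple model.

**Exclusions** (`apply_exclusions()`): participants with pooled
catch-trial accuracy strictly below 75% are removed (exactly 75% is
retained); timed-out trials stay in the record but are excluded per
trial from every likelihood. A timed-out catch trial counts as
incorrect.

## The synthetic cohort and what it does (not) show

`cohort_spec()` defaults encode the study conditions: 52 participants
per group; counterfactual generating model; group learning-rate
distributions $N(0.39, 0.05)$ and $N(0.34, 0.06)$ truncated to (0, 1);
$\beta \sim N(3, 0.5)$ truncated to (0, 10) — the report gives no
group-level $\beta$, and 3 is a mid-scale value typical of such tasks;
2% timeouts and 2% catch errors per trial as mild, realistic response
noise. Truncated-normal draws use rejection sampling. Master seed →
deterministic per-participant child seeds, so a cohort, its fits, and
the comparison are bit-reproducible end to end.

The single- and multi-cue tasks have no generative model in the original
analysis. So that accuracy summaries have realistic inputs, synthetic
cohorts use a *cue-weight responder*: a delta-rule associative learner
over the ±1-coded stimulus features (plus bias) with a softmax response.
It is a plausibility device of this package — labelled as such — and no
scientific claim rests on it.

Passing recovery tests therefore shows that the pipeline is
self-consistent — data generated under the stated conditions lead back
to the generating model and parameter ordering — not that real
participants behave like RW agents, and not that the original fitted
values are reproduced, since those depend on the deposited raw data and
unreported sampler settings.

Twenty bandit trials are deliberately weak for individual-level
recovery; the harness (`recovery_experiment()`) reports group-level
recovery (ordering of group means, selection of the generating model) as
the primary score and exposes trials-per-session as a dial — individual
recovery correlation rises steeply from 20 to 200 trials, and the test
suite requires r ≥ 0.8 at 200 trials.

## Problem sizes used by the test suite

Unit tests run the hierarchical sampler on 4–8 participants with short
chains (2 × 150–400 draws); the end-to-end checks run the study-scale
design (52 + 52 participants, 20 trials) with 2 × 300 draws and 3
replicates for the group-ordering and model-selection checks, and a
30-agent group for model recovery. These sizes were chosen as the
smallest at which the group-level claims are stable across seeds;
`recovery_experiment()` accepts larger designs unchanged.

## Known limitations

- The hierarchical sampler is JAGS; results match Stan-based fits in
  distribution but not draw-for-draw, and no divergence diagnostic
  exists.
- `fit_rw_mle()` on 20-trial sessions frequently hits the
  non-identifiability flag — a property of the design, not a defect.
- The cue-weight responder is not a model of human single-/multi-cue
  learning; accuracy tables built from synthetic cohorts describe the
  simulator only.
- The boxplot-style outlier rule (`outlier_flag()`) flags points outside
  median ± 1.5 IQR; reports based on a different whisker convention will
  differ for small samples.
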