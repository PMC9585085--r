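---
title: "Modelling instrumental avoidance in a probabilistic reversal task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling instrumental avoidance in a probabilistic reversal task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avoidrl)
```

## The task and what the package models

`avoidrl` simulates and analyses a two-option instrumental learning task in
which, on every trial, a participant chooses a left or right seat in a scene
containing two individuals; immediately afterwards one individual displays
anger, so the participant ends up either far from the angry individual (an
*avoidance* outcome) or next to them (*approach*). One response side carries
an 80% probability of avoidance, the other the complementary 20%, and the
mapping reverses at hidden block boundaries: 300 trials in 12 blocks, three
each of 20, 24, 26 and 30 trials in a shuffled order, so contingencies
reverse every 25 trials on average. A *hit* is a choice of the side
currently carrying the higher avoidance probability.

The scientific question the models address is whether such avoidance
learning is *counterfactual*: whether people also update the value of the
option they did not choose, using the outcome it would have delivered
(here, exactly the complement of the obtained one, since one individual is
always angry).

## The learning models

Both learners track a per-side instrumental value $Q$ and a habit
(choice-kernel) value $H$. With reward coded $R = 1$ for avoidance and
$R = 0$ for approach, the chosen side $c$ follows the delta rule

$$Q_{t+1}(c) = Q_t(c) + \alpha\,(R_{c,t} - Q_t(c)),$$

while the unchosen side $u$ is either left untouched (the **simple** model)
or updated with the same learning rate against the foregone outcome
$R_{u,t} = 1 - R_{c,t}$ (the **counterfactual** model). Independently of
outcome, the habit values move toward the just-made choice,

$$H_{t+1}(c) = H_t(c) + \alpha_{hab}\,(1 - H_t(c)), \qquad
  H_{t+1}(u) = H_t(u) + \alpha_{hab}\,(0 - H_t(u)),$$

and both components mix into the decision value
$D = w\,H + (1 - w)\,Q$. Choices follow a two-option softmax
$P(a) = 1/(1 + e^{(D(b) - D(a))\beta})$. A parameter-free **random**
baseline chooses each side with probability 0.5, so its log-likelihood is
$n_{valid}\ln 0.5$ ($-207.94$ for a fully responding 300-trial session).

Free parameters, supports and defaults:

| parameter | meaning | support | prior |
|---|---|---|---|
| $\alpha$ | learning rate on $Q$ | $[0,1]$ | Beta(1.1, 1.1) |
| $\alpha_{hab}$ | habit/perseveration rate on $H$ | $[0,1]$ | Beta(1.1, 1.1) |
| $\beta$ | softmax inverse temperature | $[0,\infty)$ | Gamma($k=1.2$, $\theta=5$) |
| $w$ | perseverance weight mixing $H$ into $D$ | $[0,1]$ | Beta(1.1, 1.1) |

### Numerical choices

* **Initialization.** $Q$ starts at 0.5 per side and $H$ at 0. The decision
  value is reported as 0.5 per side for the first trial; note that
  recomputing $D = wH + (1-w)Q$ at the initial state gives $(1-w)/2$ per
  side instead. Both versions are equal across sides, so the first-trial
  choice probability is 0.5 either way and the likelihood is unaffected;
  from the first update onward $D$ is always the recomputed mixture.
* **Within-trial order.** The choice probability uses the pre-feedback
  state; $Q$, then $H$, are updated after feedback; $D$ is recomputed last.
* **Invalid trials.** When no response is registered, no feedback is shown,
  so invalid trials contribute no likelihood term and trigger no update.
* **Log floor.** Per-trial log choice probabilities are floored at
  $\log 10^{-12}$ so the objective stays finite when a large $\beta$ makes
  an observed choice numerically impossible.
* **Conservation.** Under counterfactual updating with the symmetric start,
  $Q(\text{left}) + Q(\text{right}) = 1$ at every trial, since the summed
  update is $\alpha(1 - \sum Q) = 0$; this is a useful internal consistency
  check and holds in `sequence_log_likelihood(..., trace = TRUE)` output to
  floating-point accuracy.

## Fitting

`fit_subject()` minimizes the prior-weighted negative log-likelihood
$-\ell(\theta) - \sum \log \pi(\theta)$ — i.e. MAP estimation, which is how
"weighting the negative log-likelihood with prior distributions" is made
precise here. Optimization is bounded local search (L-BFGS-B with
finite-difference gradients) from the fixed starting point
$\alpha = \alpha_{hab} = w = 0.5$, $\beta = 1$, inside the box
$[\varepsilon, 1-\varepsilon]^3 \times [\varepsilon, 30]$ with
$\varepsilon = 10^{-6}$ (the inset keeps the Beta(1.1, 1.1) log-densities
finite; the $\beta$ cap excludes a region the gamma prior makes negligible
while preventing degenerate step-function likelihoods). The single fixed
start is the default; `fit_options(restarts = n)` adds prior-drawn starting
points for robustness studies. Both the raw log-likelihood and the
penalized objective are stored, so model comparison can use either;
`likelihood_matrix()` defaults to raw log-likelihoods, which is also how
the models are compared against the parameter-free random baseline.

`posterior_predictive()` replays the fitted agent on the subject's own
block schedule 100 times by default with fresh Bernoulli feedback and
averages the per-trial choices (full generative replay). Because
"trial-by-trial generation" can also be read as conditioning on the
observed history, a deterministic conditional variant
(`type = "conditional"`) is exposed; the generative replay is the default
because it is the variant whose mean hit curves can be compared with real
learning curves without reusing the observed choices.

## The synthetic-data generator

The generator is the package's stand-in for real participants and defines
the conditions every simulation-based check runs under:

* **Task**: the default `task_config()` is the study design above
  (80/20 contingency, 12 shuffled blocks, 300 trials). The first block's
  optimal side is drawn uniformly per participant and reversals toggle it
  deterministically; contingencies attach to the response side, not to
  stimulus identities (identities are not modelled at all).
* **Population**: `default_population()` mixes two counterfactual-learner
  profiles in 154:60 proportion, matching the fitted group medians of the
  study sample — a "non-explicit" majority ($\alpha = 0.50$,
  $\alpha_{hab} = 0.084$, $\beta = 1.50$, $w = 0.78$) and an "explicit"
  minority ($\alpha = 0.74$, $\alpha_{hab} = 0.06$, $\beta = 1.84$,
  $w = 0.63$). Simulated cohorts from these profiles reproduce the
  qualitative group pattern: higher hit rates and steeper hyperbolic
  learning curves in the explicit group.
* **Ratings**: `generate_ratings()` enumerates the 40 evaluation-task
  scenario instances per subject (10 identity pairs × 2 anger positions ×
  2 seat positions; 20 approach, 20 avoidance) and draws ratings from
  `approach_mean + avoidance_effect·[avoidance] + subject intercept +
  residual`, truncated to [0, 100], with condition means 25.34 and +37.05.
  The dispersion components are not identified by condition means alone;
  `subject_sd = 8` and `residual_sd = 10` were fixed once as typical
  visual-analog-scale spread, small enough that truncation shifts the
  configured means by an order of magnitude less than the generator's own
  sampling error at the cohort sizes used.
* **Response quality**: misses and anticipations (reaction time < 100 ms)
  can be injected at configurable rates, and reaction times are lognormal
  (median 450 ms) purely to exercise the exclusion filters — subjects are
  excluded for responding on fewer than 90% of trials or for anticipating
  on more than 15% of valid responses. Reaction times never enter the
  models.

What the generator does *not* emulate: stimulus identities and their
sequencing constraints, attention or fatigue drifts, reaction-time
dynamics, and any coupling between questionnaire covariates and learning
parameters. Passing simulation-based checks therefore demonstrates the
estimation and analysis machinery is correct under the task's generative
assumptions, not that those assumptions capture every feature of real
participants.

## Behavioral statistics

Learning curves pool the first 20 trials after each reversal and regress
hits on the hyperbolic predictor $y = 1 - 1/(1 + x)$ of the 0-based
within-block trial index. Repetition analyses classify each
consecutive-valid-trial pair by the feedback at $t-1$ (win-stay =
repetition after avoidance; lose-shift = 1 − repetition after approach);
pairs are kept across block boundaries, since reversals are hidden from
participants, and only invalid-adjacent pairs are dropped. Value-based
repetition pairs each trial with the subject's mean rating (rescaled to
0–1) of the scenario class received at $t-1$; matching by exact stimulus is
not modelled because identities are out of scope. In place of
maximal random-effects mixed logistic models, the package reports
per-subject summaries, exact binomial tests against chance, and pooled
logistic fits with subject-clustered (CR0 sandwich) standard errors —
the pooled fits answer the same directional questions while keeping the
package free of mixed-model machinery that is not its contribution; the
mixed-model odds ratios of the original analyses are consequently not
quantities this package reproduces.

Parameter–covariate screening uses Spearman correlations with
Benjamini–Hochberg adjustment applied across the full parameter × covariate
matrix (the most conservative of the plausible families; adjusting per row
or column can be done by slicing the input).

## Model comparison

`friedman_test()` implements the within-subject rank statistic
$\chi^2 = \frac{12}{nk(k+1)} \sum_j R_j^2 - 3n(k+1)$ with midranks for ties
(flagged); it agrees with the reference implementation in `stats` on
tie-free data. Pairwise model contrasts use Wilcoxon signed-rank tests —
exact null for small tie-free samples, normal approximation with continuity
correction otherwise — Bonferroni-corrected for the number of pairs, and
group contrasts on parameters use the Mann–Whitney test. Effect sizes are
rank-biserial correlations throughout: for the signed-rank test
$(W^+ - W^-)/(W^+ + W^-)$, for the rank-sum test $2U/(n_1 n_2) - 1$. Both
the rank-sum statistic and the normal-approximation $z$ are reported, since
either convention appears in published reports of these tests.

## Validation design and problem sizes

The package validates itself entirely on synthetic data, at sizes chosen to
make the checks sharp yet quick on a single CPU:

* *Hand-trace equivalence*: 100 random 10-trial datasets against a naive
  independent re-implementation of the update equations, tolerance
  $10^{-12}$.
* *Parameter recovery*: 50 subjects × 300 trials with true parameters drawn
  once over the instrumental regime ($\alpha \in [0.2, 0.9]$,
  $\alpha_{hab} \in [0.02, 0.15]$, $\beta \in [3, 8]$,
  $w \in [0.05, 0.6]$); fitted $\alpha$ and $w$ rank-correlate with truth
  at $\rho \ge 0.5$. The habit rate is only weakly identified over its
  narrow realistic range — a known property of choice-kernel models at this
  trial count, not a defect of the optimizer.
* *Model recovery*: 20 subjects per generating kind (random / simple /
  counterfactual, RL generators at moderate $\beta \sim U(2, 6)$); the
  counterfactual model wins the majority of counterfactual-generated
  subjects and the random baseline keeps the majority of random-generated
  ones once the prior penalty is accounted for.
* *Contingency checks*: pooled simulations of ≥ 10,000 trials, 3σ binomial
  bounds.

## Known limitations

* Fits are per-subject MAP; no hierarchical shrinkage, no posterior
  uncertainty, no information-criterion selection (the compared RL models
  have equal complexity and the baseline is parameter-free).
* Two response options only; no eligibility traces; no reaction-time
  model.
* The pooled logistic fits with clustered errors approximate, but are not,
  the maximal random-effects models used in the original analyses.
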