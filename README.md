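# avoidrl

Simulation and model-based analysis of instrumental avoidance learning in a
two-option probabilistic reversal task. People quickly learn to keep their
distance from an angry individual even when nobody tells them there is
anything to learn; `avoidrl` provides the computational machinery to study
that behavior: a task/agent simulator, delta-rule learning models with a
habit component, per-subject MAP fitting, behavioral summary statistics,
and nonparametric model comparison. It is aimed at computational
cognitive-science researchers who want to fit these models to trial-level
choice data or run parameter/model-recovery studies on synthetic cohorts.

## The models

On each of 300 trials a participant picks the left or right seat; one side
carries an 80% probability of an *avoidance* outcome (ending up far from
the angry individual), the other 20%, and the mapping reverses at hidden
block boundaries (12 blocks, three each of 20/24/26/30 trials, shuffled).
With reward R = 1 for avoidance and 0 for approach, the chosen side c
follows the delta rule

    Q[t+1](c) = Q[t](c) + α (R - Q[t](c))

and the unchosen side u is either left untouched (**simple** model) or
updated against the foregone outcome 1 − R with the same α
(**counterfactual** model). A habit value H grows toward the just-made
choice at rate α_hab and decays for the other side; choices follow a
softmax with inverse temperature β on the mixture D = w·H + (1 − w)·Q.
A parameter-free **random** baseline (P = 0.5 each side) anchors model
comparison. Fitting minimizes the negative log-likelihood weighted by a
Gamma(1.2, 5) prior on β and Beta(1.1, 1.1) priors on α, α_hab, w (MAP).

See `vignette("avoidance-learning-models")` for the full model account,
numerical choices, and the synthetic-data generator's assumptions.

## Worked example

Simulate a 30-subject cohort from the default two-profile population
(counterfactual learners with "explicit"/"non-explicit" strategy
parameters mixed 154:60), summarize behavior, fit all models, and compare:

```r
library(avoidrl)

cohort <- generate_cohort(30, seed = 42)
summ <- behavior_summary(cohort)
round(tapply(summ$hit_proportion, summ$strategy_group, mean), 3)
#>     explicit non_explicit
#>        0.601        0.548

fits <- fit_cohort(cohort)                 # simple + counterfactual + random
m <- likelihood_matrix(fits)               # subjects x models log-likelihoods
compare_models(m)
#> Model comparison over 30 subjects
#> Friedman chi2(2) = 46.67, p = 7.35e-11
#>            model  median     min     max
#> 1         simple -196.82 -205.53 -179.34
#> 2 counterfactual -195.79 -205.54 -176.08
#> 3         random -207.94 -207.94 -207.94
#>   simple vs counterfactual: W+ = 131, z = -2.09, p_corr = 0.113, r = -0.44
#>   simple vs random: W+ = 465, z = 4.78, p_corr = 5.48e-06, r = 1.00
#>   counterfactual vs random: W+ = 465, z = 4.78, p_corr = 5.48e-06, r = 1.00
```

Both learning models beat the chance baseline for every subject (its
log-likelihood is fixed at 300·ln 0.5 = −207.94 for full responders), the
explicit-strategy group hits more often than the non-explicit group, and
the counterfactual model's median log-likelihood is the highest — at this
small cohort size the simple-vs-counterfactual contrast does not survive
Bonferroni correction, which is expected: the two models differ by a single
update rule and separate reliably only at larger n (see the model-recovery
tests).

Recovery studies and the end-to-end pipeline:

```r
truth <- sample_parameters(seed = 1, n = 25)
parameter_recovery_study(truth, "counterfactual", seed = 2)

run_pipeline(pipeline_config(seed = 1, n_subjects = 20), "out/")
```

A thin command-line wrapper over the same functions ships at
`inst/cli/avoidrl.R` (subcommands `simulate`, `fit`, `report`, `pipeline`,
`recover`).

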