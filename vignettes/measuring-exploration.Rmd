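---
title: "Measuring exploration strategies in few-armed bandit tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring exploration strategies in few-armed bandit tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`banditmetrics` is a simulation and measurement toolbox for the question:
how well do few-armed bandit tasks measure individual differences in
exploration strategies? It implements three widely used paradigms — a
Horizon task, a drifting two-armed bandit, and a four-armed restless bandit
— together with their cognitive models, and the psychometric machinery
(parameter recovery, test–retest reliability, convergent validity,
reward-optimality analysis, and confirmatory factor models) needed to judge
the resulting parameters as *measurements* rather than only as model fits.

Because desk-scale work cannot assume access to participant data, the
package is exercised end-to-end on a synthetic cohort whose subject-level
parameters follow a known two-factor latent structure. Every number the
package reports is computed by running the pipeline; nothing is looked up.

## The three tasks and their reward structures

**Restless bandit.** Four arms pay noisy rewards around latent means that
follow a mean-reverting random walk,

$$\mu_{j,t+1} = \lambda\,\mu_{j,t} + (1-\lambda)\,\theta + \varepsilon_t,
\qquad \varepsilon_t \sim N(0, \sigma_{\text{innov}}^2),$$

with decay rate $\lambda = 0.9836$, center $\theta = 50$, innovation sd
$2.8$ (variance $7.84$), and observation noise sd $4$; one round of 200
choices. Candidate walks are rejection-sampled until the identity of the
best arm changes at least 5 times and no arm stays best for more than 80
consecutive trials, so that exploration stays worthwhile throughout. These
thresholds are the package's reading of "variability in which arm is best";
they are configurable in `restless_config()`.

**Horizon task.** Eighty rounds crossing horizon length (1 vs 6 free
choices after 4 forced choices) with the information condition (forced
sampling [1,3] vs [2,2]). Arm means are stable within a round; every
horizon-by-information cell uses the same multiset of absolute mean gaps
{30, 20, 12, 8, 4} (each gap four times per cell), and the side of the
better arm and of the less-sampled arm are fully counterbalanced, which
makes the two arms exactly equally rewarding on grand average. The observation-noise
magnitude for this task defaults to sd 4 (matching the other two tasks)
and is exposed in `horizon_design()`.

**Two-armed bandit.** Thirty rounds of ten choices. Within a round each
arm's mean is stable or drifts as a random walk (all four combinations
occur); initial mean gaps are biased toward 8 points, and rounds are
re-sampled until the average absolute latent gap stays at or below 15.
Per-step drift sd defaults to 2 and initial means center on 50; both are
configurable in `twoarmed_design()`.

Realized rewards are rounded to integers and clipped to [1, 99] by default
(slot-machine point displays); latent means keep full precision. All three
generators are pure functions of `(config, seed)`.

## Learning and choice models

The restless and two-armed models learn by Kalman filtering. For the chosen
arm the gain is
$K = (V + \sigma_{\text{innov}}^2)/(V + \sigma_{\text{innov}}^2 +
\sigma_{\text{noise}}^2)$; its mean moves toward the reward by fraction
$K$ and its variance becomes $(1-K)(V + \sigma_{\text{innov}}^2)$, while
unchosen arms keep their means and accumulate $\sigma_{\text{innov}}^2$ of
variance per trial. In the restless bandit only, posterior means
additionally decay toward the center between trials
($E \leftarrow \lambda E + (1-\lambda) C$). All learner constants are fixed
at the generating values and never fitted. Priors default to the mean of
the generating process (50) with a prior variance equal to the walk's
stationary variance ($\sigma_{\text{innov}}^2/(1-\lambda^2) \approx 241$)
for the restless bandit and to the drift variance accumulated over one
round ($4 \times 10 = 40$) for the two-armed bandit — the natural
"generating values" where the fixing policy leaves the exact numbers open.

Choices follow:

* **Restless:** a UCB softmax,
  $P(j) \propto \exp\{\tau E_j + \beta\sqrt{V_j + \sigma_{\text{innov}}^2}\}$,
  with value-guided weight (inverse temperature) $\tau$ and directed
  exploration bonus $\beta$ (negative $\beta$ = uncertainty avoidance).
* **Two-armed:** a logistic regression on the belief-derived predictors
  $E_1-E_2$ (value-guided), $\sqrt{V_1}-\sqrt{V_2}$ (directed), and — in
  the *original* variant only — $(E_1-E_2)/\sqrt{V_1+V_2}$
  (random/Thompson exploration), plus a side-bias intercept. The
  original variant carries all three predictors; the improved variant
  drops the random-exploration term, whose predictor is nearly collinear
  with the value difference.
* **Horizon:** learning is plain averaging of the four forced rewards; the
  first free choice is a logistic regression on $E_1-E_2$ and the scaled
  information difference $(I_1-I_2)/4 \in \{-0.5, 0, 0.5\}$. The original
  variant fits one block per horizon condition, each with its own
  intercept, and scores
  exploration as long-minus-short weight differences; the improved variant
  uses only the long-horizon rounds and reports the weights themselves.

For *simulating* Horizon sessions the agent also needs a policy for the
later free choices of long rounds: it keeps updating running means and
counts and applies the same condition-specific weights. This matches the
first-free-choice model exactly on the trials that are ever fit.

## Fitting

`fit_mle()` maximizes the exact choice likelihood with bounded multi-start
L-BFGS-B (bounds: logistic weights in [−50, 50], $\tau \in [0,5]$,
$\beta \in [-20, 20]$; starts uniform in bounds under a fixed seed, one
start always at the null model) followed by a short Newton polish.
Probabilities are floored at $10^{-12}$ inside the optimizer only; the
public likelihood raises an error on an exactly-zero-probability choice.
All three likelihoods are convex in their free parameters (logistic and
conditional-logit forms), so the 5-start default is redundancy rather than
necessity; the heavy pipeline loops use 2 starts.

`fit_hierarchical()` provides partial pooling as penalized marginal
optimization: independent Normal group distributions per parameter,
alternating subject-level MAP estimation with EM updates of the group
moments via a Laplace approximation of each subject's posterior. The group
moments are initialized from the interior MLEs only (unpenalized estimates
of weakly identified subjects pile up at the bounds) and the variance
update is stabilized by two pseudo-subjects at the initialization scale.
This reproduces the two behaviors the hierarchical approach is used for:
shrinkage of outlier subjects toward the group, and group means with 95%
intervals. It is an empirical-Bayes approximation, not MCMC; posterior
tails beyond the Laplace approximation are out of scope.

A practical note on identifiability: at the default group scales the
restless cohort is strongly uncertainty-avoiding ($\beta < 0$ for almost
every subject), and simulated agents then lock onto a single arm. A locked
session carries little information about $\tau$ — the Fisher information
gives a per-subject standard error around 0.17 against a true
between-subject sd of about 0.07 — so no estimator can push the
recovery correlation for $\tau$ much beyond ~0.6 under these conditions.
The package reports what the data allow and does not tune the conditions.

## The synthetic cohort

`generate_synthetic_cohort()` draws, per subject, two latent factors
(value-guided and directed exploration; default correlation 0.64) and
builds each task parameter as
$\theta = m + s\,(L f + \sqrt{1-L^2}\,u)$ with group mean $m$, sd $s$, and
loading $L$. Defaults: group means at the scale of hierarchically fitted group
effects in adult samples (two-armed 0.13/0.15; restless 0.15/−0.41), sds
at half the mean's magnitude, and measurement-model loadings of
0.597/0.535/0.696 (value) and 0.137/0.444/0.891 (directed) for the
Horizon, two-armed and restless indicators respectively. Session-level scores mix stable and session-specific
components of both the factors and the uniquenesses so that (i) the
session-level loadings equal $L$ and (ii) every true parameter correlates
exactly $\rho$ (default 0.7) across sessions; $\rho = 1$ makes the two
sessions' true parameters identical. The restless inverse temperature is
floored at 0.01.

One deliberate calibration: the Horizon value weight is expressed per
point of value difference, and its cohort default is 0.15 (sd 0.075) —
chosen once so that simulated first free choices are stochastic but
clearly above chance (a much larger per-point weight would make them
deterministic). The directed weights live on the ±0.5 information scale.
Short-horizon blocks are derived from the long blocks (value scaled by
0.8, directed lowered by the default long-minus-short difference of
0.81), with independent subject-level deviations when difference-score
recovery is analyzed.

What the generator does *not* emulate: practice effects, attention lapses,
within-session drift of strategies, heavy-tailed parameter distributions,
and any questionnaire or working-memory structure. Passing tests therefore
show that the pipeline is correct and well calibrated under a clean factor
model — not that real data will be as well behaved.

## Psychometrics

* `switch_probability()` — proportion of consecutive within-round free
  choices that differ; round boundaries never form pairs.
* `p_optimal()` — proportion of free choices of an arm attaining the
  maximal latent mean on that trial; ties count as optimal (the lenient
  convention).
* `chance_inclusion_threshold()` — the binomial 95th-percentile chance
  criterion used for participant inclusion.
* `icc()` — ICC3(C,1) and ICC3(A,1) from the explicit two-way ANOVA sums;
  the consistency form is invariant to session-constant shifts, the
  agreement form penalizes them.
* `convergent_matrix()` — pairwise-complete Pearson correlations (Pearson throughout),
  computed on session 1 by default.

## Recovery, optimality, latent structure

`parameter_recovery()` simulates one session per subject from known
parameters on a fixed reward set, refits (MLE or hierarchical), and
reports two matrices: generative-vs-fitted correlations (diagonal =
recovery) and the correlations among the fitted parameters themselves,
which is where estimation trade-offs appear — with independent generative
draws the original two-armed variant shows a value↔random trade-off near
−0.85 that the improved variant removes, while cross-correlations between
generative and fitted parameters of different names converge to zero for
both variants.

`reward_grid()` simulates mean earned reward over a value-guided ×
directed grid (default axes 0–1 and −2..2, 21 points each; 200
repetitions with repetition seeds shared across cells so contrasts are
paired). The restless bandit simulates 50 choices per repetition by
default (full length by configuration). `horizon_info_value()` runs the
deterministic forced-exploration probe: on unequal-information long
rounds, choosing the less-explored arm and observing its fifth reward,
counting how often the sample-mean best-arm estimate flips and how often a
flip points to the truly better arm. Sample means (not model posteriors)
define "best" here, matching the Horizon model's learning rule.

`fit_cfa()` fits factor models by maximum likelihood on the indicator
correlation matrix, with unit-variance factors (so loadings are reported
standardized), free factor correlations, and optional correlated residuals
for same-task parameter pairs. It reports the model chi-square and df, CFI
against the independence baseline, RMSEA (0 at df = 0), and a full-data
Gaussian BIC. Residual variances are bounded below at $10^{-6}$; a
solution on that bound is flagged as a Heywood case and marked
inadmissible rather than silently accepted. `compare_models_bf()`
approximates the Bayes factor as $\exp(\Delta\text{BIC}/2)$ — the
unit-information-prior argument — and labels the approximation
explicitly in its output.

## Numerical choices and degenerate inputs

* Softmax utilities are max-subtracted; probabilities sum to 1 to 1e−12.
* Optimizer: L-BFGS-B with `factr = 1e4` plus up to three damped Newton
  steps for interior solutions (matches an IRLS logistic oracle to ~1e−8).
* Zero between-subject variance makes the ICC undefined; it is flagged.
* Constant measure columns yield `NA` correlations and are listed in the
  matrix's `flagged` attribute.
* Ties in best-arm identification (`which.max`) resolve to the first arm.
* Reward-set rejection sampling raises an error after a bounded number of
  attempts instead of looping forever.

## Problem sizes

The shipped analyses use sizes chosen to make correlations stable while
staying desk-scale: 200 subjects for recovery, 100 for the reliability
pipeline, 175 (the study's final sample size) for the latent comparison,
40–100 repetitions per optimality cell, and a 12-subject demonstration
cohort for the end-to-end pipeline determinism check. All sizes are
arguments.

## Known limitations

* Hierarchical inference is empirical-Bayes/Laplace, not full MCMC;
  interval calibration is approximate (coverage ~0.85–0.95 in the shipped
  simulations).
* The restless $\tau$ is weakly identified under the default cohort, as
  discussed above; this is a property of the study conditions, not of the
  estimator.
* The two- vs one-factor comparison at the default loadings and factor
  correlation 0.64 yields modest evidence (log10 BF typically 0–4 at
  N = 175): with the Horizon directed loading near zero and strongly
  correlated factors, the one-factor model is a close competitor on clean
  synthetic data.
* The CFA analyzes correlation matrices; mean structures and FIML
  missing-data handling are out of scope.
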