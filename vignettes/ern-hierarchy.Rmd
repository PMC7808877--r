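---
title: "A hierarchical measurement model for the error-related negativity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical measurement model for the error-related negativity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

The error-related negativity (ERN) is a negative deflection of the
response-locked ERP, maximal over frontocentral sites roughly 10–110 ms
after an erroneous response. It is usually quantified as a single
error-minus-correct mean amplitude per participant and treated as a unitary
trait indicator regardless of the task used to elicit it. `ernfactor`
implements the psychometric machinery needed to test that assumption when
the same participants complete several speeded-response task variants (here:
four Flanker variants — arrows, faces, unpleasant pictures, pleasant
pictures):

1. score single trials from response-locked epochs,
2. screen outliers and aggregate trials into consecutive 60-trial *units*
   (five per 300-trial task), computing a unit-level error-minus-correct
   ERN that can be missing when a unit contains no error,
3. fit confirmatory factor models to the participants × (task × unit)
   matrix — one single-factor model per task, a flat model with all 20
   units on one factor, and a second-order model in which task factors
   load on a General ERN,
4. prune misfitting models by dropping as few indicators as possible,
5. estimate regression-method latent scores and relate them to personality
   trait domains via a multitrait–multimethod matrix and Fisher-z profile
   similarities.

Every stage also exists in generative form, so the whole chain can be
exercised on synthetic data with known ground truth.

## The generative and measurement model

Per participant, a standard-normal General ERN factor $g$ and task factors

$$\eta_t = a_t\, g + \sqrt{1 - a_t^2}\, d_t, \qquad d_t \sim N(0, 1),$$

with per-task general loadings $a_t$. The true unit-level ERN (µV) is

$$\mathrm{ERN}_{tu} = m_t + s_t\left(\lambda_{tu}\, \eta_t +
\sqrt{1-\lambda_{tu}^2}\, \delta_{tu}\right),$$

so units have standardized loading $\lambda_{tu}$ on their task factor and
variance $s_t^2$. Correct trials are a participant baseline plus
measurement noise; error trials add the unit's true ERN. The measurement
model fitted to extracted unit scores is the matching linear factor model
$\Sigma = \Lambda \Phi \Lambda^\top + \Theta$, with
$\Phi = \gamma\gamma^\top + \mathrm{diag}(1-\gamma^2)$ in the second-order
case.

Trait domains (five general-trait domains with six facets each; five
maladaptive domains with 7/5/3/5/5 facets) are drawn jointly with $g$ and
the $d_t$ so that the correlation between each domain and each ERN factor
hits a configured target; facets are `loading × domain + residual`.

### Key parameters and defaults

| parameter | default | unit | rationale |
|---|---|---|---|
| `n_participants` | 93 | — | the study size the pipeline is designed around |
| `n_trials_per_task`, `n_units` | 300, 5 | — | 10 blocks of 30 trials; 60-trial units |
| `general_loadings` | .75/.70/.80/.60 | — | spread inside the .6–.8 band typical of task-battery ERN correlations (.4–.7 between grand averages) |
| `unit_loadings` | 0.65 | — | yields inter-unit correlations ≈ .2–.45 after trial noise, matching the reported .2–.6 range |
| `ern_mean` | −6/−5/−5/−4 | µV | typical error-minus-correct differences |
| `ern_sd` | 3 | µV | between-person spread of the true unit ERN |
| `trial_noise_sd` | 8 | µV | single-trial EEG noise; gives unit-score reliability ≈ .5 at ~9 errors/unit |
| `presentation_start`, `presentation_step` | 200/20 ms (arrow), 400/40 ms (pictures) | ms | staircase: +step below 75% accuracy, −step above 90% |
| `target_error_rate` | 0.175 | — | midpoint of the 75–90% accuracy band |
| `trait_ern_corr` | ±0.25 on hypothesized pairs | — | a "small-to-medium" coupling, large enough to be recoverable at n = 2000 |
| `facet_loading` | 0.7 | — | conventional facet-domain loading |

The error-probability model is a logistic, monotone-decreasing function of
presentation time (scale 40 ms arrow / 80 ms pictures), shifted per
participant by a Gaussian ability offset (SD = one staircase step). Only
the accuracy band itself is dictated by the task design; the psychometric
function is this package's modelling choice.

## Epoch scoring

Epochs span −400..798 ms at 500 Hz (600 samples). Scoring is the mean of
the Fz/Cz average over 10–110 ms after baseline correction over −400..−200
ms; all window endpoints are inclusive on the 2 ms grid (a "200 ms window"
is 101 samples). Channel-level artifact criteria: adjacent-sample step
> 50 µV, max−min > 200 µV in any 200 ms window, max−min < 0.5 µV in any
100 ms window; all strict inequalities, evaluated with sliding windows
(tiled windows available by flag — sliding is the stricter reading). The
simulator adjusts each synthetic epoch so the scored value equals the
trial's target amplitude exactly, making the generator–scorer round trip an
identity in the artifact-free case; injected artifacts (250 µV step, 3
µV/sample drift, flat channel) exercise each criterion.

## Trial pipeline conventions

* Outlier screening is done within participant × task × result bins; the
  boundary is strict (`> 3 SD` removed, exactly 3 SD kept), a single pass,
  no re-screening after removal. Bins with fewer than two trials are left
  unscreened and logged.
* Unit membership follows the original trial number (`ceiling(index/60)`);
  removals never shift other trials' units.
* A unit ERN requires at least one error and one correct trial; otherwise
  the cell is missing with reason `no-error-unit`. The grand average pools
  the whole task and is therefore defined whenever the task has any error.
* Between-subject screening masks, column by column and independently,
  values beyond 3 SD of the cross-participant column mean (single pass).
  Masking a grand-average column never touches unit columns — the columns
  are treated as independent measurements.
* Participant × task exclusions are supplied explicitly (a sidecar table),
  never inferred.

## The FIML CFA engine

The engine maximizes the casewise Gaussian log-likelihood over each case's
observed-variable pattern (full-information maximum likelihood), grouped by
missingness pattern with cached sufficient statistics, using analytic
gradients and `nlminb`. Means are modeled (free indicator intercepts); a
flag-free alternative is simply to center the data. The chi-square is
computed against the saturated Gaussian model — closed form with complete
data, EM-estimated under missingness — and the incremental-fit baseline is
the independence model (free means/variances), whose FIML solution
separates per variable.

Identification: by default every latent variable is standardized — factor
variances 1, and in the second-order model the first-order disturbances are
`1 − γ²` so task factors stay standardized. A marker scheme (first loading
fixed to 1, variances free) is available; both parameterize the same
covariance family and reach the same maximized likelihood (tested to
1e−8). Note the naive "general variance 1, disturbances free, all loadings
free" scheme is *not* identified — each task factor would retain a free
scale — which is why the standardized constraint is built in.

Numerical choices: principal-axis starting values per factor block from the
saturated covariance; jittered restarts only when a start fails (up to 9);
convergence accepted at `nlminb` code 0 or a scaled gradient norm below
1e−4; relative tolerance 1e−12 (tightened to 1e−15 where closed-form
agreement is asserted); non-positive-definite proposals are rejected with a
large penalty. Negative residual variances (Heywood cases) or |γ| > 1 flag
the solution inadmissible; inadmissible or non-converged fits are never
"good-fitting".

Fit indices use the standard formulas — CFI, TLI, RMSEA with a 90% CI from
inverting the noncentral chi-square, SRMR over the covariance moments
standardized by the saturated variances, AIC/BIC counting all free
parameters including means. The good-fit rule is the inclusive conjunction
CFI ≥ .95, TLI ≥ .95, RMSEA ≤ .08, SRMR ≤ .08; undefined indices
(saturated models) fail the rule. Robust (scaled) test statistics are not
implemented: the synthetic study conditions are exactly multivariate
normal, where scaled and plain statistics estimate the same quantity; this
is a known limitation for heavy-tailed real data.

## Model search and scores

`prune_search` fits all `choose(p, k)` drop-k single-factor candidates at
level k = 1, 2, … (default `max_drop = 2`), stopping at the first level
with any good-fitting candidate and picking the lowest AIC and BIC among
them. When AIC and BIC disagree — which requires candidates with different
parameter counts at the same level, possible after non-converged exclusions
— both are reported and BIC wins (the consistency-favoring criterion).
Full-enumeration at level 2 is used rather than restricting to near-miss
pairs; with at most `choose(7, 2) = 21` candidates this costs little and
guarantees minimality. Models with three indicators are just-identified
(zero df) and cannot be judged by fit; they are fitted directly when
scores are needed but never pruned.

Latent scores are regression-method (Thurstone) estimates
$\hat\xi = \Phi_\xi \Lambda^\top \Sigma_{oo}^{-1}(x_o - \mu_o)$ evaluated
on each case's observed pattern, so missing cells shrink the score toward
zero rather than dropping the case. Task ERN scores come from the per-task
(possibly pruned) single-factor models, the General ERN from the
second-order model; the second-order model's task scores are emitted as a
separately labeled variant.

## Validity summaries

The MTMM matrix crosses the five ERN measures with the ten trait domains
(Pearson r, pairwise-complete). Effect sizes follow the conventional
inclusive thresholds |r| ≥ .10/.30/.50. Convergent validity is the share of
hypothesized pairs reaching at least a small effect in the expected
direction; discriminant validity the share of non-hypothesized pairs below
.10. The hypothesis set pairs the arrow task and General ERN with
Neuroticism/Conscientiousness (and maladaptive counterparts), the social
task with the interpersonal domains, the unpleasant task with
negative-affect domains, and the pleasant task with Extraversion/reversed
Detachment — 16 expected and 34 unexpected pairs. Expected signs are
negative (enhanced ERN = more negative amplitude with higher trait) except
for the reverse-keyed maladaptive domains. No multiple-testing correction
is applied: interpretation is by effect size, with p-values reported for
transparency.

Profile similarity Fisher-z transforms each measure's five within-instrument
trait correlations and correlates the z-profiles between measures (Pearson,
per the alerting-r construction; rank-based alternatives would discard the
spacing information the construction is meant to keep). Correlations with
|r| > 0.9999 are clamped with a warning so the transform stays finite.

## What the synthetic data do and do not show

The generator reproduces the *structure* of the study — sample size, block
and unit layout, adaptive difficulty, missing units arising naturally from
error-free units, a genuine second-order latent structure, correlated trait
domains — under exact multivariate normality, homogeneous noise, and linear
couplings. Passing tests therefore demonstrate that the pipeline recovers
known structure under the stated conditions; they cannot establish
robustness to non-normal single-trial noise, drifting electrode impedance,
task-order effects, or nonlinear trait–ERN relations, none of which are
modeled.

Two small-sample properties are worth knowing. First, with 20 indicators
at n = 93 the ML chi-square is inflated relative to its asymptotic
distribution and unit indicators have reliability near .5, so per-task and
second-order good-fit verdicts at the demo size vary across seeds — one or
two of the four tasks may need pruning, much as one task did in practice on
real data of this size. At n = 500 the engine separates the flat and
second-order structures essentially always (the acceptance simulation
requires ≥ 95% of 50 replications). Second, score-based trait correlations
are attenuated by factor-score reliability, so an imposed latent coupling
of .25 appears as roughly .15–.20 in estimated scores; convergent
percentages at n = 93 are accordingly noisy.

## Problem sizes used by the checks

The test suite and the acceptance script use: the full demo at n = 93; 200
replications at n = 500 for loading recovery (mean absolute bias < 0.02);
50 replications at n = 500 for structure discrimination; n = 2000–5000
draws for moment-convergence and score-quality checks; and toy problems
with hand-computed expectations for every arithmetic rule (3-SD screening,
unit binning, ERN differencing, triad closed form, regression-score
algebra, Fisher-z profiles).
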