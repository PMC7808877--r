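# ernfactor

Hierarchical psychometric analysis of the error-related negativity (ERN).

The ERN is a negative event-related-potential deflection occurring ~10–110
ms after an erroneous response, commonly used as a trait-like individual
difference marker. When the same people complete several task variants, a
natural question is whether the ERN is one construct or a hierarchy: unit
scores within a task measuring a task-specific factor, task factors loading
on a General ERN. `ernfactor` implements that full analysis chain for
researchers in psychophysiology and personality neuroscience:

* **Synthetic data with ground truth** — participants, adaptive Flanker-style
  behavior (presentation-time staircase holding accuracy in the 75–90%
  band), trial-level amplitudes generated from a known second-order latent
  model (task factor `η_t = a_t·g + √(1−a_t²)·d_t`; unit ERN
  `m_t + s_t(λ_tu·η_t + √(1−λ_tu²)·δ_tu)` in µV), facet-level personality
  scores from correlated trait domains, and optionally response-locked
  epoch waveforms.
* **Epoch scoring** — baseline correction (−400..−200 ms), channel-level
  artifact rejection (50 µV step, >200 µV per 200 ms, <0.5 µV per 100 ms),
  mean Fz/Cz amplitude over 10–110 ms.
* **Trial pipeline** — 3-SD outlier screening within participant × task ×
  result bins, 60-trial unit binning by trial number, error-minus-correct
  unit and grand-average ERNs (missing when a unit has no error), and
  columnwise 3-SD between-subject screening.
* **A FIML CFA engine** — full-information maximum likelihood over each
  case's observed-variable pattern with analytic gradients; saturated model
  by EM under missingness; CFI, TLI, RMSEA (90% CI), SRMR, AIC, BIC;
  the good-fit conjunction CFI ≥ .95, TLI ≥ .95, RMSEA ≤ .08, SRMR ≤ .08.
* **Model search** — iterative pruning that drops as few indicators as
  possible to reach good fit, tie-broken by AIC/BIC.
* **Validity** — regression-method (Thurstone) latent scores
  `Φ Λ' Σ⁻¹ (x − μ)`, an ERN × trait multitrait–multimethod matrix with
  Cohen effect-size flags, convergent/discriminant hypothesis scoring, and
  Fisher-z trait-profile similarities between ERN measures.

## Worked example

```r
library(ernfactor)
cfg <- population_config(seed = 11)   # 93 participants, 4 tasks x 300 trials
run <- run_pipeline(cfg, out_dir = "demo_out")
print(run)
```

```
ERN pipeline run: n = 93 participants, seed 11 (2.9 s)
  structure fits:
    arrow         chi2(5) =    2.93  CFI 1.000  SRMR 0.034  good
    social        chi2(5) =    1.54  CFI 1.000  SRMR 0.027  good
    unpleasant    chi2(5) =    1.93  CFI 1.000  SRMR 0.030  good
    pleasant      chi2(5) =    2.19  CFI 1.000  SRMR 0.031  good
    flat          chi2(170) =  197.04  CFI 0.821  SRMR 0.087  not good
    second_order  chi2(166) =  136.42  CFI 1.000  SRMR 0.070  good
  convergent 75% / discriminant 53% of hypothesis pairs
```

Each per-task single-factor model fits, the flat model forcing all 20 units
onto one factor does not, and the second-order model with a General ERN
over task factors fits — the hierarchical pattern the generator encodes.
At this sample size the verdicts are genuinely seed-dependent (unit scores
have reliability ≈ .5 and the ML chi-square is inflated for 20 indicators
at n = 93); some seeds require pruning a unit from a task, which
`run$task_searches` then documents. The bundle written to `demo_out/`
contains the fit table, search audit, ERN matrix with missing-cell reason
codes, latent scores, the MTMM matrix, e.g.

```
           neuroticism conscientiousness extraversion agreeableness
arrow            -0.16             -0.25         0.05         -0.26
unpleasant       -0.29             -0.08        -0.14         -0.25
general          -0.22             -0.09        -0.23         -0.30
```

(negative r = larger, more negative ERN with higher trait; the generator
imposes |r| = .25 couplings on hypothesized pairs, attenuated in estimated
scores), and per-instrument profile-similarity matrices. Reruns with the
same seed are byte-identical.

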