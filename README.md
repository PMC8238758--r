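# memroc

Recognition-memory ROC models and remember/know analysis for image
memorability.

## The problem

Some photographs of real-world scenes are remembered (or forgotten) by
almost everyone who sees them: an image's *memorability* — its hit rate in
large-sample recognition experiments — behaves like an intrinsic item
property. What memorability does **not** say is what kind of memory
supports those recognitions: a graded sense of *familiarity*, or
*recollection* of specific episodic detail. `memroc` provides the full
analysis chain used to ask that question from trial-level confidence and
remember/know data, for researchers in recognition memory and
psychometrics.

## The models

Confidence-rating data (1 = sure new ... *B* = sure old) are summarized
as a 2 × *B* table of old/new response counts and fitted with two
signal-detection accounts:

- **DPSD** (dual-process signal detection). An all-or-none recollection
  process succeeds with probability *Ro* and forces the most-confident
  "old" response; otherwise familiarity is a Gaussian strength signal with
  sensitivity *d′* (equal variance). Cumulatively,

  P(response ≥ j | old) = Ro + (1 − Ro)(1 − Φ(cⱼ₋₁ − d′)),
  P(response ≥ j | new) = 1 − Φ(cⱼ₋₁),

  with ordered criteria c₁ < … < c_{B−1}. Nonzero *Ro* bends the ROC into
  a "hockey stick" and pushes the zROC slope below 1.

- **UVSD** (unequal-variance signal detection). One strength dimension;
  old items are Normal(*d′*, *Vo*) against a standard-normal foil
  distribution: P(response ≥ j | old) = 1 − Φ((cⱼ₋₁ − d′)/Vo). With
  *Vo* = 1 it reduces to the equal-variance model, identical to DPSD with
  *Ro* = 0.

Both models are fitted by maximum likelihood (product-multinomial, B + 1
free parameters each), checked with the likelihood-ratio *G*-test
(df = B − 3), and compared by BIC with a preregistered-style rule: a model
wins only with the lower BIC in ≥ 80% of subjects *and* an acceptable
*G*-test in > 80%.

Remember/know (R/K) statements for "old" responses — and their
detailed/unfamiliar (D/U) counterparts for "new" responses — are scored
with the scaled difference

Y = (r − k) / (r + k) ∈ [−1, 1],

which respects the interdependence of the two proportions, and contrasts
between memorability bins are tested with one-sided JZS Bayes-factor
*t* tests (Cauchy prior on the standardized effect, scale √2⁄2 by
default). An exploratory stage ranks images by memorability into
quantiles of equal trial numbers, refits both models per quantile, and
predicts quantile rank from each model's parameters with
proportional-odds ordinal regression.

A generative observer simulator (`simulate_experiment()`) with
memorability-linked *Ro*, *d′* and statement behaviour makes every stage
testable without human data.

## Worked example

```r
library(memroc)

design <- design_exp2()                       # 42 subjects, 180 old + 180 foils
pop    <- observer_population(design$n_subjects, model = "dpsd", seed = 11)
trials <- simulate_experiment(design, pop, seed = 101)
run    <- run_pipeline(trials, run_config(out_dir = tempfile("memroc_"),
                                          seed = 101))
run
#> <memroc_run>
#>   subjects kept: 42 (excluded: 0)
#>   winning model: INCONCLUSIVE
#>   Yold high vs low (hits): BF10 = 3.92e+05, d = 1.01
#>   outputs: /tmp/.../memroc_...

run$selection
#> <model_selection over 42 subjects>
#>   lower BIC:    DPSD 79%  UVSD 21%
#>   G acceptable: DPSD 93%  UVSD 69%
#>   winner: INCONCLUSIVE
```

The simulated population has recollection rising with memorability, and
the pipeline recovers exactly the qualitative signature that motivates
the dual-process reading: the scaled difference for hits is strongly
higher for high- than low-memorability images (one-sided BF₁₀ ≈ 4 × 10⁵,
Cohen's d_z ≈ 1.0), DPSD attains the lower BIC in 79% of subjects — a
clear majority, though short of the 80% rule, hence "inconclusive" — and
the quantile regression explains rank variance slightly better with DPSD
parameters, with the recollection coefficient dominating:

```r
run$quantile_regression$summary
#>   model  chi2 df  p_model r2_nagelkerke r2_adjusted  n converged
#> 1 dpsd   68.2  2 1.52e-15         0.898       0.891 30      TRUE
#> 2 uvsd   66.0  2 4.59e-15         0.890       0.882 30      TRUE

tidy(run$quantile_regression$dpsd)
#>   term   estimate std_error     z    p_value std_coef
#> 1 ro         36.5      7.67  4.75 0.00000199     3.42
#> 2 dprime     13.8      2.87  4.80 0.00000160     3.22
```

All stage tables (exclusions, per-subject/per-image descriptives, fits,
Bayes factors, quantile fits, regression coefficients) are written as CSV
under `out_dir` with a JSON manifest recording the configuration, seed
and a config hash.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch on a freshly simulated
deep-encoding experiment (the design above) under the given seed —
exclusion, descriptives, DPSD/UVSD fits and model selection, scaled
differences with Bayes factors, and the quantile ordinal regression — and
writes the JSON report to `--out`.
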