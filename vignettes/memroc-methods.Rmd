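---
title: "Models and methods in memroc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in memroc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`memroc` analyses trial-level recognition data — confidence ratings on a
1 ("sure new") to B ("sure old") scale plus remember/know-type
statements — as a function of item memorability, the item's hit rate in
large-sample recognition experiments. This vignette documents the models,
the estimation machinery, the synthetic-data generator, and the design
choices made where the methodology left room.

## Signal-detection models of the rating ROC

The sufficient statistic for all model fitting is the 2 × B table of
response counts for old and new items (`rating_counts()`). Responses
above the scale midpoint are classified "old".

**DPSD.** Recollection is an all-or-none threshold process: with
probability `Ro` an old item is recollected, which is assumed to produce
the most-confident "old" response (the classical high-confidence
recollection assumption; it is what generates the "hockey-stick" ROC and
a zROC slope below 1). With probability `1 - Ro` the decision falls back
on familiarity, a Gaussian strength signal of mean `d'` and unit
variance. New items are standard normal. Cumulatively,

$$P(\text{resp} \ge j \mid \text{old}) = Ro + (1 - Ro)\,
  \bigl(1 - \Phi(c_{j-1} - d')\bigr), \qquad
  P(\text{resp} \ge j \mid \text{new}) = 1 - \Phi(c_{j-1}).$$

**UVSD.** A single strength dimension; old items are
$\mathcal N(d', Vo^2)$, new items standard normal. `Vo = 1` recovers the
equal-variance model, which is *exactly* the DPSD model with `Ro = 0`:
this equivalence is enforced to numerical precision and used as a test
surface.

### Likelihood and estimation

The likelihood is product-multinomial: the old and new rows are
independent multinomials given the model's bin probabilities. The
multinomial coefficient is omitted throughout; it is identical for both
models on the same data and cancels in every comparison the package
makes (G, BIC differences, likelihood-ratio tests).

`fit_rating_counts()` maximizes the likelihood over an unconstrained
reparameterization:

- `Ro` by logit (bounded to [0, 1]);
- DPSD `d'` by softplus (familiarity is a positive-evidence process, so
  `d' >= 0`; UVSD `d'` is unconstrained);
- `Vo` by log;
- criteria as first threshold plus log-gaps, which enforces strict
  ordering. Gap parameters are clamped to `[-20, 20]` before
  exponentiation so the criteria remain strictly increasing in finite
  arithmetic.

Ordered-threshold likelihoods are multimodal in awkward corners of the
parameter space, so optimization uses BFGS with an analytic gradient and
10 restarts: one from a moment-based start (criteria from corrected
cumulative false-alarm rates, `d'` from the mean z-difference, `Vo` from
the zROC slope) and nine from deterministically jittered copies. The
jitters come from a fixed local seed, so fitting consumes no global RNG
state and is bit-reproducible without a seed argument. The `converged`
flag reports the optimizer status of the best restart honestly; tables
with all mass in a single bin for both rows are flagged
`identifiable = FALSE` rather than raising an error.

### Goodness of fit and model comparison

The G-test is $G = 2\sum O \ln(O/E)$ over cells with positive observed
counts; zero-observed cells contribute nothing and expected counts are
not floored. Both models carry `B + 1` free parameters (`B - 1` criteria
plus two signal parameters), so

- df $= 2(B-1) - (B+1) = B - 3$ (3 on the 6-point scale), and
- BIC $= -2\log L + (B+1)\ln N$ with $N$ the total trial count — the
  most common sample-size convention; `N` is recorded in the fit object
  so alternatives are auditable.

Matching parameter counts across models keeps the BIC comparison about
fit, not dimension. (The UVSD model is still the more flexible of the
two in functional form; that asymmetry is exactly why the package also
offers the quantile-regression comparison below.)

`select_winning_model()` implements the preregistration-style rule: a
model wins when it has the lower BIC in at least 80% of subjects *and*
its G-test is non-rejected (p ≥ 0.05) in more than 80%; anything else is
"inconclusive". With the rule's thresholds exposed as arguments, the
same function expresses laxer or stricter variants.

## Descriptive statistics

Hit and false-alarm rates are corrected away from 0 and 1 by adding 0.5
to both counts and 1 to both totals before forming proportions; the
correction is applied uniformly wherever rates are formed (per subject,
per bin, per image), since the methodology gives no reason to treat the
levels differently. `d'` is the difference of inverse normals of
corrected rates. AUC integrates the empirical ROC (anchored at (0,0) and
(1,1)) by the trapezoidal rule, which needs no model of the curve; the
zROC omits cumulative rates of exactly 0 or 1, where the inverse normal
diverges.

Memorability bins follow fixed thresholds: scores above 0.75 are "high",
above 0.55 "mid", the rest "low". Because the defining inequalities are
strict on both sides, scores exactly at a boundary are not covered by
them; `memroc` sends boundary scores to the lower bin, a fixed
convention that makes binning deterministic. Subjects performing no
better than chance are flagged by a one-sided exact binomial test on
overall accuracy at α = 0.05.

Data collected with a separate old/new decision plus 3-point confidence
are mapped onto the 6-point scale as `("new", c) -> 4 - c`,
`("old", c) -> 3 + c` by `read_trials(dialect = "oldnew3")`.

## Scaled differences and Bayes factors

Because a "know" statement implies "not remember" (and vice versa), the
two proportions are interdependent; the scaled difference
$Y = (r - k)/(r + k)$ folds them into one outcome in [−1, 1], positive
when remember/detailed statements dominate. It is undefined at 0/0:
such subject × bin cells return `NA` and are dropped pairwise from group
contrasts — the methodology offers no imputation rule and none is
invented. Summary tables report both the mean of per-subject scaled
differences (subjects weighted equally) and the scaled difference of
pooled counts (trials weighted equally); published tables do not always
say which aggregate they show, and the two differ in general.

Directional hypotheses (e.g. "memorable images are *more* associated
with remember statements") are tested with one-sided JZS Bayes factors:
under H1 the standardized effect follows a Cauchy prior with scale
√2⁄2 — the conventional "medium" default, exposed as `prior_scale` since
the choice is substantive — truncated to the hypothesized direction
(with its mass renormalized), the standard convention for directional
alternatives. The marginal likelihood is computed by adaptive quadrature
of the noncentral-t density over the prior, split at the likelihood peak
so narrow modes cannot be missed. Effect sizes are Cohen's
$d_z = \bar d / s_d$, the paired-design convention; the output flags it
as `cohens_d` computed from differences, since $d_z$ and $d_{av}$ are
not interchangeable.

## Quantile ordinal regression

The exploratory stage asks which model's parameters carry more
information about memorability. Items are rank-ordered by memorability
(ties broken by image id, so the assignment is stable under input order)
and packed into Q = 30 quantiles of equal trial totals; trials are
pooled over subjects within a quantile — pooling, rather than averaging
per-subject fits, is what gives each quantile enough trials for a stable
ROC — and both models are fitted per quantile. Quantile rank (1..Q,
ordered) is then regressed on each model's two signal parameters (`Ro`,
`d'` for DPSD; `d'`, `Vo` for UVSD) with a cumulative-logit
(proportional-odds) model; criteria are deliberately excluded, matching
the parameters a substantive comparison cares about.

The ordinal likelihood is maximized directly (thresholds as first value
plus log-gaps, predictors standardized internally); `MASS::polr` serves
as an independent cross-check in the test suite rather than as the
implementation, because with one observation per rank the model carries
Q − 1 thresholds for Q observations and off-the-shelf fitters are
fragile in that regime. Reported per model:

- the likelihood-ratio χ² against the intercepts-only model, with df =
  number of predictors;
- Nagelkerke's rescaled pseudo-R², plus an adjusted variant applying the
  usual df correction $1 - (1-R^2)(n-1)/(n-p-1)$ — the "adjusted R²"
  convention for such regressions is not standardized, so both values
  are emitted;
- standardized coefficients as raw coefficient × predictor SD
  (latent-scale standardization), invariant to predictor rescaling.

With a strongly rank-aligned predictor the model approaches perfect
separation and the ML estimate diverges; the optimizer's iteration cap
then acts as a soft barrier and `converged = FALSE` is reported. The
*comparison* of standardized magnitudes remains meaningful in that
regime, but absolute coefficient values should not be interpreted.

## The synthetic observer

`simulate_experiment()` generates the stated world the package is tested
in: a deep-encoding remember/know design of 42 subjects with 180 targets
and 180 foils (`design_exp2()`), or a larger shallow-encoding design of
45 subjects with 330 + 330 (`design_exp1()`), on a 6-point scale, with
each image a target for half the subjects and a foil for the other half.
Item memorability defaults to three equal uniform bins
(0.30–0.55, 0.55–0.75, 0.75–0.95), giving bin means near 0.45 / 0.65 /
0.85, the regime of the published memorability databases.

Observer parameters are linked to memorability `m`:
$Ro(m) = \text{logit}^{-1}(-2.1 + 2.2m)$,
$d'(m) = 0.2 + 1.0\,m$ (floored at 0 for DPSD), criteria
(−1.0, −0.3, 0.8, 1.4, 2.0), and
$P(D \mid \text{"new"}, m) = \text{logit}^{-1}(-2.0 + 2.5m)$. These
defaults were chosen once to land in the empirical regime of a
facilitated-encoding scene-memory experiment — hit rates rising from
roughly 0.57 (low memorability) to 0.78 (high), false-alarm rate near
0.21, and the recollection share among hits rising from about 0.43 to
0.57 — and are not revisited. Between-subject heterogeneity jitters link
intercepts (SD 0.25) and criteria (common shift, SD 0.1), modest values
typical of individual differences in confidence usage.

Statement generation needs conventions the source methodology does not
supply, and they are stand-ins, not claims:

- under DPSD, "R" is emitted only on recollection events; all other
  "old"-classified responses are "K". A DPSD observer therefore emits no
  false-alarm "R" statements — a recollect-to-reject-free world,
  consistent with doubts about recollect-to-reject in simple item
  recognition;
- UVSD observers have no latent recollection event, so "R" is emitted
  exactly at the maximal confidence bin, keeping model-recovery studies
  possible under both generative accounts;
- every "new"-classified response (correct rejection or miss) draws "D"
  with probability $P(D \mid m)$ from a single logistic link — not a
  recollection mechanism.

Each trial consumes one recollection uniform, one normal and one
statement uniform in fixed order, so a DPSD observer with `Ro = 0` and a
UVSD observer with `Vo = 1` produce identical response columns from the
same seed — a property the test suite checks. Each subject runs on an
independent stream seeded from `(master seed, subject index)` (kept
below 2³¹), so any subject's data can be regenerated in isolation.

What the generator does **not** emulate: encoding-phase behaviour
(presentation times, concurrent tasks, feedback), semantic image
categories and the per-category boundary adjustments they motivated,
response times, personally-familiar items, and any generative account of
*confidence* for K statements. A green test therefore establishes that
the analysis machinery recovers what this model family generates — not
that human statement behaviour follows these conventions.

## Numerical choices, degenerate inputs, limitations

- Bin probabilities are floored at 1e-300 inside log-likelihoods; G-test
  denominators at 1e-12 inside gradients.
- `scaled_difference(0, 0)` is `NA` by design, never an error; zero
  variance in a Bayes-factor test is an error unless the mean is also
  zero, in which case t = 0 (data exactly at the null).
- Count tables need at least two nonzero bins per row for the models to
  be identifiable; worse tables are flagged, not refused.
- Quantiles that lose all old or all new trials are skipped with a
  warning and excluded from the regression.
- The G-test's χ² reference is asymptotic; when `Ro` is weakly
  identified (criteria that place substantial false-alarm mass in the
  top bin), boundary estimates inflate the rejection rate above its
  nominal level at moderate trial counts. The calibration test runs in a
  well-identified regime; users fitting low-performance data should
  expect mild anticonservatism.
- BIC model comparison inherits the usual caveat that parameter *count*
  is not parameter *flexibility*; the quantile regression exists
  precisely to complement it.
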