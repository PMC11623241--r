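---
title: "Multidimensional nominal response models for observer studies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional nominal response models for observer studies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the statistical model the package implements, the
numerical choices behind the sampler and the information criteria, what the
synthetic-data generator does and does not emulate, and the design decisions
that were genuinely open.

## 1. The model family

An observer study produces one nominal response per (case, rater) pair.
Write i = 0..I−1 for cases, j = 0..J−1 for raters, s for the case's
ground-truth class and t for a candidate response class, with C classes.
Every variant defines a logit vector over t and maps it to probabilities
through the softmax,

$$\Pr(r_{ij} = t \mid s) = \frac{\exp(z_{ijst})}{\sum_{h=1}^{C} \exp(z_{ijsh})}.$$

The conventional nominal response model (`nrm_2pl`) uses a scalar ability
per rater, `z = α_it θ_j + β_it`; its one-parameter reduction (`nrm_1pl`)
drops α.  The multidimensional variants make the ability a C×C matrix per
rater, indexed by (ground truth, response): `mdnrm_orig` has
`z = θ_jst + β_is`, and the two-parameter subtypes add a discrimination
term — `mdnrm_a` (`α_is θ_jst + β_s`), `mdnrm_b` (`α_s θ_jst + β_is`), and
`mdnrm_r` (`α_is θ_jst + β_is`).  The diagonal entries θ_jss measure rater
j's tendency to answer correctly when the truth is s; off-diagonal entries
measure specific confusion patterns.  Priors are Normal(0, 2) on every θ
and β entry and either Gamma(shape 2, rate 2) or half-Normal(scale 10) on
every α entry.

Two structural degeneracies of the family as defined are worth knowing:

* **β cancels in all four MDNRM variants.**  The easiness index never
  involves the response class t, so it is a constant inside the softmax.
  The likelihood is therefore invariant to β, whose posterior equals its
  prior.  The package preserves the family exactly as defined — it does
  not re-parameterize — and the property is turned into a test (the
  compiled likelihood is bit-stable under arbitrary β changes, and after a
  real fit the β margins pass a Kolmogorov–Smirnov comparison against
  Normal(0, 2)).  It even serves as a free correctness check of the
  sampler.  For users who want an identified easiness, the constructor
  offers `beta_by_response = TRUE`, which indexes β by the response class
  (as the NRM variants do); this is deliberately non-canonical and unused
  anywhere else.
* **θ cancels in `nrm_1pl` for the same reason** (it is constant over t).
  The variant is kept for completeness of the family.

### Gamma parameterization

The discrimination prior is stated as a gamma distribution with
"alpha = 2 and beta = 2" without naming rate versus scale.  The package
uses shape 2, rate 2 — the parameterization of the probabilistic-programming
stacks this model family is usually fitted with — giving prior mean 1, the
conventional discrimination scale.  The "truncated normal" option is the
half-normal with scale 10, as glossed in the literature on discrimination
priors.

## 2. Inference

No probabilistic-programming engine is available to this package, so it
carries its own gradient-based sampler, written in C++:

* **Target.**  The joint log posterior with α transformed to the log scale
  (`u = log α`, Jacobian folded in), so the positive support is exact by
  construction.  Analytic gradients; verified in the test suite against
  central differences for every variant.
* **Kernel.**  A No-U-Turn sampler (slice variant, maximum tree depth 10)
  with dual-averaging step-size adaptation to a 0.8 target acceptance
  statistic, and a diagonal mass matrix estimated during warmup in
  expanding windows (75-iteration initial step-size-only buffer, windows
  doubling from 25 iterations, terminal buffer of 10% of warmup), each
  window shrinking the variance estimate slightly toward unit scale.
  These are the standard defaults of mature NUTS implementations; the
  source literature for this model family specifies only chain counts, not
  kernel tuning.
* **Initialization** is an independent prior draw per chain.  Divergent
  transitions after warmup are counted per chain and always reported.
* **Determinism.**  Each chain owns a Mersenne-Twister generator seeded
  deterministically from `mcmc_config$seed`, so the same configuration
  reproduces bit-identical draws; the R session's RNG state is never
  touched.
* **Defaults** follow the production settings used for studies of this
  size: 8 chains × 8,000 retained draws after 1,000 warmup iterations.
  Desk-scale work (tests, recovery experiments) reduces chains and draws;
  where the package's own acceptance checks do this, the reduction is a
  runtime-budget decision made before looking at results, and the checked
  quantities (R-hat thresholds, interval coverage, paired RMSE ordering)
  are stable at the reduced sizes.

Convergence is screened with rank-normalized split-R-hat (the larger of
the bulk statistic and the statistic of the median-folded draws), with the
plain split version available behind a flag.  The acceptance threshold for
this family is R-hat < 1.10 across every parameter.

## 3. Model comparison

Both criteria are computed from the S×N pointwise log-likelihood matrix
stored with every fit and are reported on the deviance scale (−2·elpd), the
scale on which values around 1,000 arise for 900 three-class responses.

* **WAIC**: `lppd = Σ_n log mean_s exp(ll_sn)` (log-sum-exp evaluated with
  max subtraction), `p_waic = Σ_n var_s(ll_sn)` with the S−1 denominator,
  score `−2(lppd − p_waic)`, standard error `√(N · var_n)` of the pointwise
  deviance contributions.
* **PSIS-LOO**: per observation the raw importance log-weights are the
  negated log-likelihoods; the `M = min(⌈0.2S⌉, ⌈3√S⌉)` largest are
  replaced by expected order statistics of a generalized Pareto
  distribution fitted to their excesses over the (M+1)-th largest weight,
  truncated at the raw maximum.  The GPD fit is the Zhang–Stephens
  profile-likelihood estimator with the weakly-informative shape
  regularization (equivalent to 10 pseudo-observations at k = 0.5) used by
  the reference implementations.  The fitted shape k̂ is reported per
  observation and k̂ > 0.7 observations are counted and warned about.
  Ties with the cutoff weight are left unsmoothed; an observation whose
  weights are exactly uniform falls back to its in-sample lppd with
  k̂ = NaN and a warning.

The implementation was validated against an independent reference
implementation on shared random matrices (agreement ~1e−10 for WAIC and
elpd_loo and for every k̂); those frozen numbers are the oracle in the
test suite.  Ranking ties are broken by model label so comparisons are
deterministic.

## 4. The simulator and what a green test establishes

`simulation_config()` describes a complete I×J design: ground truths drawn
from a prevalence vector (uniform by default), responses drawn from the
chosen variant's softmax probabilities at true parameters drawn from the
priors (or fixed by the caller).  Defaults mirror a realistic chest-CT
observer study — 6 raters, 150 cases, 3 classes, near-uniform prevalence —
so that recovery experiments carry an amount of information per parameter
comparable to real use.

The default generative discrimination prior is Gamma(2, 2).  This is a
deliberate choice: half-Normal(10) *truths* routinely produce |z| > 20 and
near-deterministic responses, which no real observer study resembles; the
half-normal remains available as a *fitting* prior, which is how it is
used in practice.  Where a recovery experiment fits the same variant and
priors that generated the data, posterior calibration theory applies
exactly: the fraction of 94% HDIs covering the truth should be 0.94 up to
replication noise, and this is what the acceptance suite checks (together
with the paired decrease of diagonal-θ RMSE when I doubles).

What the generator does **not** emulate: missing responses, case-difficulty
drift, reader fatigue or learning, correlated errors between raters, and
label noise in the ground truth.  A green recovery test therefore
establishes the correctness and calibration of the *implementation under
its own generative assumptions* — not that those assumptions hold for any
particular clinical dataset.

β is non-identified in MDNRM variants (§1), so recovery reports flag the
family rather than pretending a per-draw comparison is meaningful; with
truths drawn from the prior, HDI coverage of β is still nominal, which is
itself a useful check that the sampler reproduces the prior.

## 5. Numerical and interface choices

* Softmax and all log-sum-exp computations are max-subtracted; likelihoods
  are computed in log space throughout.
* `hdi()` is the sliding-window shortest interval on sorted draws
  (⌈prob·n⌉ points, lowest window on ties); it collapses to a point for
  constant draws and converges to the sample range as prob → 1.
* `pd()` splits draws exactly at zero evenly between the signs — unbiased
  under ties, irrelevant (measure zero) for continuous posteriors.
* **Significance rule.**  The analysis couples PD with a 94% HDI; the
  package's decision rule for "significant" is *0 outside the 94% HDI of
  the difference*, the standard HDI existence test.  PD is always reported
  alongside, so any other threshold can be applied; no multiplicity
  correction is built in — threshold choice across many contrasts is
  explicitly left to the analyst.
* HDIs and PD are computed on pooled chains, matching standard practice.
* Class, case, and rater indices are 0-based everywhere in the public
  interface, matching the coding of observer-study response files and the
  conventional layout of published ability tables (`rad_index`, `index1`,
  `index2`).
* Missing responses (a rater skipping a case) are accepted by the data
  model and simply absent from the likelihood; complete designs are not
  required.
* The number of classes may be overridden upward when a small sample does
  not realize every legal class.
* Fits persist as draw arrays plus a human-readable JSON sidecar carrying
  the spec, configuration, dimensions, and sampler diagnostics, sufficient
  to re-create summaries without refitting.

## 6. Known limitations

* The sampler is single-machine and sequential over chains; very large
  studies (I in the thousands) will be slow compared to GPU-backed stacks.
* The half-normal(10) discrimination prior induces a funnel-like geometry
  (weakly identified per-item log-discriminations); the adaptive sampler
  handles it at the study sizes tested (zero post-warmup divergences), but
  step sizes an order of magnitude smaller than under the gamma prior are
  normal, and runtimes grow accordingly.
* wAIC/LOO standard errors assume independent pointwise contributions;
  with only J raters per case the effective replication is limited, and
  comparisons between models of similar score should lean on the reported
  ± values, not the point ranking alone.
* Vector-valued abilities and multivariate-normal priors over the ability
  matrix are out of scope (natural extension points of the family).
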