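---
title: "The self-consistency model and its analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The self-consistency model and its analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmdiag)
```

## The model

`scmdiag` studies a question that arises wherever experts read the same
material twice: when a radiologist re-reads a mammogram months later and
reverses their call, which of the two diagnoses should anyone trust? The
package implements the self-consistency model (SCM) of such two-alternative
expert decisions, a synthetic reader-study generator built on it, and the
statistical pipeline that tests the model's qualitative predictions on
two-session rating data.

The SCM pictures an expert facing case $i$ as sampling a fixed, odd number
$n$ of cues (from the image, from memory) and deciding by cue majority.
Each cue independently points to the correct option with probability
$p_i$, the case's *cue validity*. Accuracy is then the upper binomial tail

$$P(p, n) = \sum_{h = m}^{n} \binom{n}{h} p^h (1 - p)^{n - h},
  \qquad m = \tfrac{n + 1}{2},$$

confidence is the complement of the sample standard deviation of the
sampled cue proportion $\hat p = h / n$,

$$\widehat C = 1 - \sqrt{\hat p (1 - \hat p)} \in [0.5, 1],$$

and because a second reading is an independent cue sample, the probability
of giving two different answers is

$$I = 2 P (1 - P).$$

Three structural facts drive everything else:

* $I$ and $\widehat C$ depend on the case only through its ambiguity
  $|p - 0.5|$, not through whether the majority is *right*. A "perfectly
  wicked" case ($p = 0$) is answered wrongly, consistently, and with
  maximal confidence.
* Majority voting amplifies: for $n \ge 3$, $P > p$ when $p > 0.5$ and
  $P < p$ when $p < 0.5$ (the Condorcet jury theorem applied to cues). The
  observed expert consensus $\widehat P_i$ is therefore a more extreme,
  but identically ordered, image of the latent $p_i$.
* Given two conflicting decisions from one expert, the more confident one
  is more often correct on kind cases ($p > 0.5$) and more often wrong on
  wicked ones ($p < 0.5$); in an environment with mostly kind cases,
  maximum-confidence slating beats choosing at random.

These yield four testable predictions: (1) inconsistency is an inverted-U
function of consensus, (2) confidence is a U function of consensus, (3)
confidence and inconsistency are negatively related, and (4) the
confidence rule helps on kind and hurts on wicked cases.

## Numerical choices in the core

`prob_correct()` evaluates the tail through the binomial survival function
rather than explicit summation, so it is exact to double precision for the
small $n$ a human plausibly samples and stable far beyond ($n = 1001$ is
covered by tests). Even $n$ is rejected outright instead of adding a
tie-break: with odd $n$ the majority is always defined and the accuracy
expression stays exact. The expected confidence reported by
`prediction_grid()` plugs $p$ into the confidence function, which is how
the model's theoretical curves are constructed; an `expectation = "exact"`
mode averages the confidence of $\hat p$ over the binomial distribution of
$h$ for readers who want the finite-$n$ expectation (the two agree as $n$
grows).

## What the generator emulates — and what it does not

`simulate_reader_study()` produces long-format two-session rating tables
with the structure the pipeline assumes. Its defaults describe a
spine-style study: 13 experts, 300 cases of which 50 are positive
(prevalence 1/6), every expert reading every case in both sessions (3900
repeated assessments), confidence on a 2-point scale. A mammography-style
configuration is one argument away (`confidence_scale(5)`, incomplete
per-expert case subsets via `expert_design()`).

Choices that the underlying data sources do not pin down, fixed here once
and documented:

* **Cue-validity mixture.** Neither dataset reports the distribution of
  $p_i$. We draw kind-case validities as $0.5 + 0.5\,\mathrm{Beta}(2, 2)$
  and wicked ones as $0.5\,\mathrm{Beta}(2, 2)$ — unimodal, mostly
  moderate ambiguity, no atoms at the deterministic endpoints — with a
  kind fraction of 0.8, comfortably a "kind environment" while leaving
  enough wicked cases to stratify on.
* **Cues per expert.** $n = 9$ by default: small enough that repeated
  readings disagree at realistic rates (the generated median per-expert
  inconsistency sits near the 13–21% seen in practice), large enough that
  skill shows. Heterogeneous per-expert $n$ is opt-in.
* **Confidence binning.** The mapping from model confidence to an elicited
  level is unknown; we use equal-width bins on $[0.5, 1]$, configurable
  edge by edge.
* **Truth and wickedness.** Truth is drawn independently of $p_i$ at the
  stated prevalence. `wicked_positive_bias` optionally couples them
  (repeated-reading designs sometimes reuse only disease-free cases), with
  the marginal prevalence preserved.

Reproducibility contract: every record's cue draw comes from a seed that
is a deterministic hash of (global seed, expert index, case index,
session), so adding experts to a design never changes existing records.
The hash spreads the session index with a large multiplier and the first
uniform after reseeding is discarded; without this, streams seeded from
adjacent integers are visibly correlated and the two sessions' draws are
not exchangeable (the bias is on the order of several percent in the
disagreement rate — a property test guards it).

The generator emulates design structure, not imaging: no reading times, no
delay effects between sessions (sessions are exchangeable by
construction, which real second readings need not be), no per-expert bias
or skill drift, independent cues. Passing tests on synthetic data
therefore show that the pipeline recovers the model's signatures when the
model is true — not that real readers satisfy the model.

## Case statistics

`summarize_cases()` computes, per case, the consensus $\widehat P_i$
(proportion of correct initial diagnoses), mean elicited confidence, and
inconsistency $\widehat I_i$ (proportion of paired readers who changed
their call). Session 1 is the default basis for $\widehat P_i$ and
confidence, with an explicit `session = 2` switch; the two are never
silently pooled. Mean confidence conditions on *all* session-1 ratings,
not only on paired ones — a documented choice where the convention is
ambiguous. Cases with no paired readings get `I_hat = NA` and a flag, not
a zero. Kind/wicked classification uses strict thresholds
($\widehat P_i > 0.6$ kind, $\widehat P_i < 0.4$ wicked) with the closed
band in between labelled intermediate: excluded from kindness-stratified
contrasts, retained everywhere else. Cases read by fewer than
`min_raters` readers are flagged low-precision rather than reweighted.

## The confidence rule

`mcs_choice()` resolves each conflicting pair toward the more confident
decision. Equal confidences on a conflict are genuinely undetermined; the
default policy flips a seeded coin, flags the tie, and the evaluation
reports the tie count, so the choice is auditable and unbiased (forcing
`first` or `second` is available). `evaluate_rule()` scores improvements
per conflicting pair as $\{-1, 0, +1\}$ against the first or second
diagnosis, or against a random chooser whose accuracy on a binary conflict
is exactly 0.5 — entered analytically, not simulated. Improvements are
aggregated as weighted means per case and per expert (weight = number of
conflicting pairs) and summarized by weighted quartiles computed via
cumulative-weight interpolation, exactly equal to expanding each weighted
point into unit copies.

## Hierarchical inference

The regression family mirrors the prediction structure: logistic or
Gaussian outcomes with crossed random intercepts for experts and cases —
`M1` (`changed ~ 1`), `M2` (`changed ~ P_c + P_c^2`), `M4`
(standardized confidence `~ P_c + P_c^2`), `M5`
(`changed ~ confidence_1`), `M7` (`rule_correct ~ kindness` among
conflicting pairs). $\widehat P$ is centered at 0.5 before squaring, so
the quadratic coefficient reads directly as curvature around chance;
confidence enters standardized (an ordinal treatment of the discrete
scales is a possible refinement; sign structure, not coefficient values,
is the target here). Priors are weakly informative and configurable:
Normal(0, 5²) on fixed effects of standardized predictors, half-Normal(0,
2²) on random-intercept and residual SDs.

The default engine is Gibbs/slice MCMC through JAGS (2 chains; split-chain
convergence checked via the potential scale reduction factor, warning
above 1.1, never silently accepted). `method = "ml"` fits the identical
structure with `glmmTMB` and approximates the fixed-effect posterior by a
multivariate normal at the estimate — orders of magnitude faster, used for
the repeated refits of parameter-recovery and coverage tests.
`variance_components_report()` compares the case and expert
random-intercept SDs through the posterior of their ratio and asserts a
direction only when the 95% interval excludes 1.

The pooled effect of the confidence rule over a random baseline is
summarized by `bayes_one_sample_ttest()`: the posterior of
$\delta = \mu / \sigma$ under a Cauchy prior on $\delta$ (scale
$\sqrt 2$, the conventional "ultrawide" setting) and Jeffreys'
$1/\sigma$. Because only a one-dimensional marginal is needed, the
posterior is computed by dense quadrature on a $(\delta, \log\sigma)$
grid (1501 × 501 points, $\pm 4$ log-units around the sample SD, midpoint
CDF for symmetric quantiles) — deterministic to well below the reporting
precision, with no sampler to tune. Zero-variance input makes the
$\sigma$ integral improper; the function then anchors the grid at a
nominal scale and warns rather than failing, so degenerate strata surface
visibly.

## Problem sizes used in the test suite

Monte-Carlo checks of the closed forms use $10^5$ replicates (three
binomial standard errors as tolerance). The regression-sign checks run on
a generated study of 100 experts × 200 cases (kind fraction 0.8, 5-point
scale) with 2 × 800 retained MCMC draws after 600 warm-up iterations —
enough that the posterior sign probabilities of interest are effectively
0 or 1, while a full fit stays in the minutes. Parameter-recovery checks
use the fast ML engine at 60 experts × 80 cases with 8 replicates.
Exhaustive-enumeration oracles cover all $2^n$ cue outcomes for
$n \le 11$.

## Known limitations

* The SCM is deliberately minimal: equally informative, independent cues
  and a shared $n$. The qualitative predictions survive relaxing these,
  but the package implements only the basic model (no correlated-cue or
  unequal-validity variants, no evidence-accumulation mapping).
* `M7`'s empirical analog was only partially supported in real data —
  second readings can be systematically better than first ones, which the
  exchangeable generator cannot produce; the wicked-case harm test is a
  model-level property, not an empirical claim.
* The ML engine's normal approximation can understate uncertainty for
  variance components near zero; directional conclusions about variance
  ratios should use the MCMC path.
* Real elicited confidence is ordinal and possibly expert-specific in its
  use of the scale; the linear treatment is a simplification.
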