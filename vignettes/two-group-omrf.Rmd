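---
title: "Testing network differences between two groups of ordinal responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing network differences between two groups of ordinal responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omrfdiff)
```

## The model

Cross-sectional psychological data are mostly Likert-type: binary or ordinal
items. `omrfdiff` models a set of $p$ such items with an ordinal Markov
random field (OMRF), the multivariate counterpart of the adjacent-category
logit model. Each variable $i$ has categories coded $0, \dots, m_i$; the
joint distribution over category-index vectors $x$ is the exponential-family
model

$$
P(x) \propto \exp\Big( \sum_i \mu_{i,x_i}
  + \sum_{i<j} \sigma_{ij}\, x_i x_j \Big),
$$

with category thresholds $\mu_{ic}$ (one per non-baseline category,
$\mu_{i0} = 0$ for identification, log-odds units) and symmetric pairwise
interactions $\sigma_{ij}$. The interaction term is linear-by-linear in the
category indices, which depends on the responses only through their
ordering, so the model is invariant under order-preserving recodings and
does not pretend the labels are interval-scaled. $\sigma_{ij}$ is a partial
association: $\sigma_{ij} = 0$ means variables $i$ and $j$ are conditionally
independent given the rest. When every variable is binary the model is
exactly the Ising model, with fields $\mu_{i1}$ and couplings $\sigma_{ij}$
(`enumerate_joint_pmf()` is checked against a direct Ising computation in
the test suite).

The full conditional of one variable has the closed adjacent-category form

$$
P(X_i = c \mid x_{-i}) \propto \exp\Big( \mu_{ic}
  + c \sum_{j \ne i} \sigma_{ij} x_j \Big),
$$

which is what `category_probabilities()` evaluates.

## Two groups

To compare the networks of two independent groups, every parameter is split
into an *overall* effect $\phi$ (the value a pooled analysis would estimate)
and a *difference* contrast $\delta$ (Group 2 minus Group 1), with each
group carrying half of the contrast:

$$
\theta^{(1)} = \phi - \tfrac{1}{2}\delta, \qquad
\theta^{(2)} = \phi + \tfrac{1}{2}\delta .
$$

This applies to each threshold vector and each interaction
(`derive_group_model()`). Centering the contrast evenly keeps the overall
parameter interpretable as the group average and makes "no difference"
exactly $\delta = 0$. Which label is Group 1 is taken from first appearance
in the data (overridable); the sign of every contrast depends on it, so it
is echoed in all reports.

Thresholds attach to specific categories, so a category observed in only
one group has no identifiable threshold difference. `align_categories()`
offers the two standard strategies:

* **Free** — each group's unobserved categories are squeezed out of that
  group's coding only. Group thresholds are then estimated separately and
  the threshold-difference test is disabled (there is no common scale to
  contrast).
* **Collapse** — a category unobserved in either group is merged into the
  next lower category (next higher if the lowest is missing) in *both*
  groups, preserving one shared category structure so threshold differences
  remain testable. We merge interior unobserved categories downward even
  when the other group observed them: symmetric treatment is the point of
  this mode.

## Pseudolikelihood

The normalization constant of the OMRF sums over $\prod_i (m_i + 1)$
configurations and is intractable beyond small $p$ (the package's exact
enumeration is guarded at $10^7$ states and exists as an oracle, not an
inference path). Estimation therefore replaces the likelihood with the
pseudolikelihood — the product over individuals and variables of the full
conditionals above — which preserves the model's structure while keeping
every factor one-dimensional. The resulting pseudoposterior is consistent
but is known to understate posterior variances when dependence is strong,
because overlapping conditionals use the same observations more than once;
the consequences for our own checks are discussed under *Limitations*.

## Priors

* Overall thresholds: independent beta-prime distributions on
  $e^{\mu_{ic}}$, i.e. log-density
  $a\mu - (a+b)\log(1+e^{\mu}) - \log B(a,b)$. Default $a = b = 1$ (a
  standard logistic density on the threshold scale: proper, symmetric,
  heavy enough tails not to fight the data).
* Overall interactions: Cauchy with scale 2.5 — weakly informative on the
  partial-association scale where observed values rarely exceed 1.
* Difference parameters: Cauchy slabs with scale 1.0, shared by threshold
  and interaction differences unless overridden. The Cauchy's heavy tails
  make the tests less sensitive to the scale choice.
* Inclusion indicators: either independent Bernoulli($\pi$), default
  $\pi = 0.5$ so that every configuration of differences is a priori
  equally likely, or Beta-Bernoulli($\alpha, \beta$), default
  $\alpha = \beta = 1$, which makes the *number* of included differences
  uniform and thereby corrects for multiplicity. Threshold and interaction
  families can use different indicator priors.

All of these are `prior_config()` fields and are echoed into every report.

## Spike-and-slab testing and inclusion Bayes factors

Each variable $i$ gets one indicator for its whole threshold-difference
vector (a shift in one threshold usually drags the others along, and one
test per variable limits the number of comparisons); each pair $(i,j)$ gets
one indicator for its interaction difference. Indicator 0 pins the
parameter (vector) to exactly zero — the spike is a literal point mass, and
every stored draw satisfies indicator $= 0 \iff$ parameter $= 0$.

The evidence for a difference is the inclusion Bayes factor

$$
\mathrm{BF}_{10} =
\frac{P(\gamma = 1 \mid \text{data}) / P(\gamma = 0 \mid \text{data})}
     {P(\gamma = 1) / P(\gamma = 0)},
$$

the posterior over prior odds of inclusion, estimated from the proportion
of draws with $\gamma = 1$. It averages over all configurations of the
other differences, and — unlike a significance test — can support the null:
$\mathrm{BF}_{01} = 1/\mathrm{BF}_{10} > 1$ is evidence for equivalence. A
pip of exactly 0 or 1 is beyond the resolution of $T$ draws; we clamp to
$1/(2T)$ (or $1 - 1/(2T)$) and flag the Bayes factor as a bound rather than
report an infinity. Conditional (on inclusion) parameter summaries are
withheld when an effect was included in fewer than 10 draws, to avoid
meaningless intervals.

## The sampler

`run_estimation()` (all difference parameters free) and `run_selection()`
(spike-and-slab) share an adaptive random-walk Metropolis-within-Gibbs
core:

* **Updates.** Overall thresholds and all interactions are updated by
  scalar Gaussian random-walk proposals; each threshold-difference vector
  is proposed jointly with a diagonal Gaussian (the test concerns the whole
  vector). Each sweep visits every block once in a freshly shuffled order —
  the update order is not fixed anywhere in the method, and shuffling
  avoids order artifacts at no cost.
* **Indicator moves.** Selection mode adds a pairwise Metropolis step per
  difference block: an exclusion proposal sets the parameter to zero; an
  inclusion proposal draws it from the current Gaussian proposal centered
  at zero and accepts with the pseudoposterior-times-slab over
  proposal-density ratio, times the indicator prior odds (conditional odds
  under the Beta-Bernoulli prior). This jointly traverses the
  trans-dimensional space without reversible-jump machinery, and with no
  data it reproduces the prior exactly — a property the test suite checks
  for the indicator marginals, the included-count distribution, and the
  slab shape.
* **Adaptation.** Proposal sds start at 1 and follow a Robbins–Monro recursion
  on the log scale, $\log s \leftarrow \log s + t^{-0.6}(\text{acc} - 0.44)$,
  clipped to $[10^{-3}, 10]$, during burn-in only, so the main phase has a
  fixed, valid kernel. The 0.44 target is the classic scalar random-walk
  optimum; the decay 0.6 satisfies the usual diminishing-adaptation
  conditions.
* **Phases.** Parameters start at zero. Burn-in splits in half: part one
  adapts without indicator moves (all differences free), part two adds the
  indicator moves; draws are stored only in the main phase. Defaults:
  burn-in $2 \times 2500$, main 10,000 — all configurable.
* **Reproducibility.** One seed drives a single R RNG stream used by both
  the R and C++ layers; a run is bit-reproducible given its
  `sampler_config()`.

Internally the pseudolikelihood is evaluated on deduplicated response
patterns with multiplicities (exact, and much faster when $n$ exceeds the
number of distinct patterns, as it does for Likert data), with per-variable
contributions and per-group "rest scores" cached and updated incrementally.

## The synthetic-data generator

`generate_truth()` builds the data-generating two-group model used in
simulation studies:

* Every pair's overall interaction is retained independently with
  probability `density`; retained values are drawn from an interaction
  pool. Real questionnaire fits produce right-skewed, predominantly
  positive interaction estimates; without an empirical pool we use a
  shifted-gamma surrogate, $0.05 + \Gamma(\text{shape } 1.5,
  \text{rate } 10)$ (mean 0.2, sd $\approx 0.12$), and any empirical vector
  can be supplied instead. This is a surrogate for calibration to a real
  dataset, not a reproduction of one.
* Standalone threshold targets are drawn i.i.d. normal (sd 0.75, roughly
  even 4-point Likert margins with moderate skews). A deterministic
  mean-field pass then recenters the thresholds for the realized
  interaction structure, $\mu_{ic} \leftarrow \mu^0_{ic} - c\sum_j
  \sigma_{ij}\bar e_j$ with $\bar e_j$ the standalone marginal mean, so
  that marginal category frequencies stay comparable across density
  conditions instead of drifting toward the top category as positive edges
  accumulate. This prevents confounding structural sparsity with marginal
  shifts without requiring an empirical re-fit.
* A fraction `prop_diff` of all pairs (uniformly chosen) receives an
  interaction difference with magnitude $\mathrm{Uniform}(0.1, 0.5)$ by
  default — large enough to be substantively interesting, small enough to
  be realistic for latent group differences — and a random sign. Threshold
  differences are zero in the harness, which focuses on interaction
  differences.
* `apply_marginal_safeguard()` regenerates the whole process until the
  second-most frequent category of every variable in each group has at
  least `min_second_category_count` (default 10) observations; near-constant
  items carry almost no information and would otherwise poison a replicate.
  Under the default settings resampling is rare.

Exact sampling (`sample_dataset(method = "exact")`) inverts the enumerated
CDF and is used whenever the state space fits the guard; the single-site
Gibbs alternative (default 1000 sweeps from uniform starts, one independent
chain per row) covers larger networks and is checked against exact samples
on moments.

What the generator does *not* emulate: item wording effects, local
dependence from shared stems, missing data, and the particular
threshold/interaction correlation structure of any real instrument. Passing
simulation checks therefore demonstrate correctness and power of the
machinery under a faithful OMRF world, not robustness to model
misspecification.

## Evaluation

`roc_auc()` ranks edges by posterior inclusion probability against the
ground-truth difference flags; ties get midranks (AUC via the Mann–Whitney
identity, identical to the trapezoidal area under the staircase). The AUC is
threshold-free, which matters when comparing methods whose scores are
calibrated differently.

## Numerical choices

* Enumeration guard: $10^7$ joint states (about $p = 10$ five-category
  variables); beyond it the capacity error names the count.
* Log-sum-exp with max subtraction everywhere a denominator is formed; the
  C++ fast path (one `exp`, one `log` per observation) falls back to the
  stable path when exponents approach overflow.
* Proposal-sd bounds $[10^{-3}, 10]$ keep adaptation from collapsing or
  exploding on flat stretches early in burn-in.
* Degenerate inputs fail fast: missing cells at construction, single
  observed categories at alignment, single-class labels in `roc_auc()`,
  empty chains in summaries. Empty datasets are allowed exactly where they
  mean something: prior-only runs.
* Quantiles are type-7; posterior intervals are central 95%.

## Problem sizes in the shipped checks

The test suite exercises the full battery at sizes chosen to make each
property measurable with comfortable margins: quadrature comparisons on
2-variable toys at 200,000 draws; evidence-growth runs at $p = 4$,
$n \in \{100, 500, 2000\}$ per group over 10 seeds; recovery at $p = 6$,
$n = 2000$ per group, moderately connected truth; harness cells at $p = 6$,
density 1, 30% differing edges, 20 replicates at $n \in \{200, 1000\}$. For
the evidence-growth check the overall network uses thresholds of $-1.3$:
with rarer co-occurrence each observation carries less information, which
keeps the Bayes factor at intermediate $n$ inside the resolution of a
10,000-draw posterior sample ($\mathrm{BF} < 2T - 1$) so its growth is
measured rather than censored at the reporting bound.

## Limitations

* **Understated posterior spread under dense dependence.** Because the
  pseudolikelihood reuses each observation in every conditional, posterior
  sds for interaction parameters run optimistic when the network is fully
  connected; point estimates remain unbiased in our recovery checks. Treat
  credible intervals from very dense networks as lower bounds on
  uncertainty, and expect selection to be somewhat eager on tiny effects at
  large $n$.
* Two independent groups only; no paired or multi-group designs, no
  missing data, no continuous variables.
* Inclusion Bayes factors beyond the draw-resolution bound are reported as
  flagged bounds, not exact values.
* The Metropolis kernel is robust but not the fastest mixer; for very
  large $p$ or $n$ expect long runs (gradient-based samplers are a known
  upgrade path).
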