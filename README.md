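# omrfdiff

Bayesian tests for group differences in networks of binary and ordinal
variables.

Applied network studies routinely ask whether the network estimated for one
group (say, a clinical sample) differs from another (a control sample) —
and, just as often, whether there is positive evidence that it does *not*.
Frequentist comparison tests can only fail to reject equivalence. `omrfdiff`
implements a two-group extension of the ordinal Markov random field (OMRF)
with inclusion Bayes factors, so every threshold vector and every pairwise
interaction can be tested for *difference versus equivalence* between two
independent groups, with evidence quantified in both directions.

## The model

For category-index vectors $x \in \prod_i \{0,\dots,m_i\}$ the OMRF is

$$P(x) \propto \exp\Big(\sum_i \mu_{i,x_i} + \sum_{i<j}\sigma_{ij}x_ix_j\Big),$$

with category thresholds $\mu_{ic}$ ($\mu_{i0}=0$) and symmetric partial
associations $\sigma_{ij}$; all-binary data reduce it to the Ising model.
Each parameter is split into an overall effect $\phi$ and a group contrast
$\delta$ (Group 2 minus Group 1), each group carrying $\phi \pm \delta/2$.
Spike-and-slab priors with binary inclusion indicators are placed on the
contrasts; the evidence for a difference is the inclusion Bayes factor

$$\mathrm{BF}_{10} = \frac{\text{posterior odds of inclusion}}
                          {\text{prior odds of inclusion}},$$

estimated from an adaptive Metropolis-within-Gibbs sampler over the
pseudoposterior (the intractable likelihood is replaced by the product of
adjacent-category full conditionals). $\mathrm{BF}_{01} = 1/\mathrm{BF}_{10}$
quantifies evidence for equivalence. Bernoulli(0.5) indicator priors make
every difference configuration equally likely a priori; Beta-Bernoulli(1,1)
priors make the *number* of differences uniform, which corrects for
multiplicity.

## Worked example

Two groups of 600 respondents on four 3-category items; the groups share
all thresholds and all interactions except one: the V1–V2 association
differs by $\delta = 0.6$.

```r
library(omrfdiff)
set.seed(2024)
truth <- two_group_model(
  group_model(list(c(0.2, -0.3), c(0.0, 0.1), c(-0.2, 0.2), c(0.1, 0.0)),
              {J <- matrix(0, 4, 4); J[1,2] <- 0.4; J[2,3] <- 0.3; J[1,4] <- 0.25
               J + t(J)}),
  difference_model(rep(list(c(0, 0)), 4),
                   {D <- matrix(0, 4, 4); D[1,2] <- 0.6; D + t(D)}))
d1 <- sample_dataset(derive_group_model(truth, 1), 600)
d2 <- sample_dataset(derive_group_model(truth, 2), 600)
draws <- run_selection(d1, d2, prior_config(),
                       sampler_config(main_iterations = 5000,
                                      burnin_iterations = 2500, seed = 42))
summarize_draws(draws)
```

```
<omrf_summary> mode=Collapse, n = 600/600 per group

Interaction difference tests:
  effect    pip    bf_10   bf_01      mean      sd
1 V1--V2 1.0000 1.00e+04  0.0001  0.651071 0.05265
2 V1--V3 0.0404 4.21e-02 23.7525  0.000933 0.00937
3 V1--V4 0.4292 7.52e-01  1.3299 -0.047988 0.06258
4 V2--V3 0.0432 4.52e-02 22.1481  0.001723 0.01269
5 V2--V4 0.2160 2.76e-01  3.6296 -0.021878 0.04866
6 V3--V4 0.0468 4.91e-02 20.3675 -0.001708 0.01325

Threshold difference tests:
  effect    pip  bf_10 bf_01 bf_bound
1     V1 0.0424 0.0443 22.58    FALSE
2     V2 0.0988 0.1096  9.12    FALSE
3     V3 0.0316 0.0326 30.65    FALSE
4     V4 0.0532 0.0562 17.80    FALSE
```

Reading the output: the truly differing edge V1–V2 is included in every
posterior draw (pip 1.0; its Bayes factor is reported at the resolution
bound of a 5000-draw sample, $2T-1$, as the model-averaged difference
estimate 0.65 ± 0.05 brackets the true 0.6). The five null edges and all
four threshold vectors show $\mathrm{BF}_{01}$ between 1.3 and 31 — mostly
*positive evidence for equivalence*, not merely absence of significance,
with the weakest case (V1–V4, $\mathrm{BF}_{01}=1.3$) correctly flagged as
"no evidence either way."

A command-line wrapper covers the same pipeline
(`inst/cli/omrfdiff fit|simulate|evaluate`), reading CSV/TSV with a group
column and writing JSON + CSV reports.

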