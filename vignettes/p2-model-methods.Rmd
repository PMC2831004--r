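---
title: "Bayesian p2 modelling of biological networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian p2 modelling of biological networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p2net)
```

## The model

`p2net` treats an observed undirected network on $n$ nodes as one draw
from a dyad-independent exponential random graph model. Each unordered
pair $(i, j)$ is connected independently with probability

$$\Pr(X_{ij} = 1) = \mathrm{logit}^{-1}(\theta + \alpha_i + \alpha_j),$$

where $\theta$ is a global *density* parameter (the log-odds of an edge
between two typical nodes) and $\alpha_i$ is the *sociality* of node
$i$: its propensity to form edges beyond the global density. Nodes with
positive sociality raise the probability of every edge they could take
part in. The undirected model is the single-parameter-per-node
reduction of the classical directed p1 model, whose four-cell dyad
probabilities (null, two asymmetric states, mutual, with reciprocity
$\phi$ and separate expansiveness/attractiveness effects) are exposed
as the closed-form utility `dyad_probabilities_directed()`.

Socialities are random effects, optionally regressed on nodal
covariates:

$$\alpha_i = \gamma^\top x_i + a_i, \qquad a_i \sim N(0, \sigma_a^2).$$

This p2 extension is what lets exogenous biology enter the model: with
a single binary covariate marking intrinsically disordered proteins,
$\gamma$ measures the effect of disorder on connectivity, and the $a_i$
are the residual socialities left after accounting for it. Conditional
on the random effects the dyads are independent, so the likelihood is a
product of Bernoulli terms over the $\binom{n}{2}$ pairs — the test
suite checks that it sums to one over the complete graph space at
$n = 4$.

### Priors

The prior specification is hierarchical and conjugate where possible:

* $\theta \sim N(0, \tau_\theta^{-1})$, $\gamma_k \sim N(0,
  \tau_\gamma^{-1})$, $a_i \sim N(0, \tau_a^{-1})$, with normals
  parameterized by precision $\tau = \sigma^{-2}$;
* every precision gets a $\mathrm{Gamma}(a_0, b_0)$ prior with
  $a_0 = b_0 = 0.001$, which makes the implied priors on the standard
  deviations effectively noninformative.

The covariate-effect prior mirrors the density-parameter prior
(zero-mean normal with its own gamma-distributed precision); the
hierarchy is symmetric across the three parameter blocks.

## Sampling

The posterior is explored by Metropolis-within-Gibbs
(`run_chain()`/`run_chains()`, compiled core):

* $\theta$, each $\gamma_k$ and each $a_i$ are updated with symmetric
  random-walk Metropolis steps. The full conditional of $a_i$ touches
  only node $i$'s incident dyads, so a full sweep costs $O(n^2)$
  likelihood terms overall.
* $\tau_\theta$, $\tau_\gamma$, $\tau_a$ are drawn exactly from their
  conjugate gamma full conditionals,
  $\mathrm{Gamma}(a_0 + k/2,\; b_0 + \tfrac12\sum v^2)$.
* Proposal scales adapt toward an acceptance rate of 0.44 (the standard
  target for scalar blocks) during burn-in only; adaptation is frozen
  afterwards so the post-burn-in kernel has the correct stationary law.

Default iteration counts are 50000 burn-in and 100000 estimation
iterations with thinning 10; the `"desk"` profile (2000/8000) is the
scaled-down setting used throughout the test suite and the simulation
studies in this vignette's companion tests, chosen so that a full
20-replicate recovery experiment runs in minutes on one CPU while still
passing nominal-coverage checks. Thinning exists purely to bound
memory; all estimator contracts are on the retained draws.

Chains are reproducible: the master seed deterministically derives one
seed per chain, and identical data, configuration and seed give
bit-identical draws. Parallel chains start overdispersed — $\theta$
alternates between $-4$ and $0$ and each chain draws its own
$a_i \sim N(0,1)$ starts — so between-chain agreement is informative.
A single chain started from the logit of the observed density (the
`run_chain()` default) converges faster but cannot feed the
Gelman–Rubin diagnostic.

Two modelling choices deserve note. First, there is no hard sum-to-zero
constraint on the random effects: the zero-mean prior is what
identifies $\theta$ against the mean of $a$, exactly as in the
hierarchical specification the model follows. The residual confounding
widens the $\theta$ posterior slightly; the recovery experiment
measures the resulting interval coverage directly. Second, all density
evaluations stay in log space (`plogis(log.p = TRUE)`), so extreme
linear predictors saturate smoothly instead of overflowing.

## Convergence diagnostics

`diagnostic_report()` computes, for every global parameter (and
optionally every $a_i$):

* **Geweke z**: the standardized difference between the means of the
  first 10% and last 50% of a chain. Window variances use the spectral
  density at frequency zero, estimated from a fitted AR($p$) model
  ($s(0) = \hat\sigma^2/(1-\sum\hat\phi_k)^2$, order chosen by AIC), so
  within-window autocorrelation is accounted for. $|z| > 1.96$ is
  flagged.
* **Gelman–Rubin PSRF** across chains, the plain between/within
  construction $\sqrt{((n-1)/n\,W + B/n)/W}$; values $\ge 1.1$ are
  flagged, and the same threshold gates chain pooling in
  `summarize_fit()` (overridable with `force = TRUE`).

The Raftery–Lewis run-length diagnostic is not implemented: it needs
quantile/accuracy settings that the analysis does not pin down, and the
two diagnostics above already cover the contracts the package makes
(stationarity within chains, agreement between chains).

## Posterior summaries and social nodes

`summarize_fit()` reconstructs the sociality $\alpha_i = \gamma^\top
x_i + a_i$ *per draw* before summarizing, so the reported quantiles are
quantiles of $\alpha$, not of the residual $a$ (with a near-zero
covariate effect the two coincide, but the $\alpha$ scale is the one a
biologist ranks nodes by). Quantiles use linear interpolation between
order statistics, the stock type-7 rule. A node is called **social**
when the 2.5% posterior quantile of its sociality is strictly positive
— a credibly positive contribution to edge formation, a deliberately
stricter call than a merely positive posterior mean, and the model-based
alternative to degree-cutoff hub definitions. `covariate_effect()`
reports each $\gamma_k$ with the same interval logic and a plain
verdict string ("positive effect, credible" only when the 2.5% quantile
clears zero).

## Goodness of fit

`posterior_predictive_gof()` simulates networks from draws of the
posterior (100 by default), not from a single point estimate: the
posterior-predictive check is the Bayesian-coherent version of
comparing observed structure to model simulations, and it propagates
parameter uncertainty into the envelope. The statistic checked is the
degree distribution — the sufficient statistic of this model — as the
fraction of nodes at each degree from 0 up to the largest degree
observed or simulated, with explicit zeros. The observed curve is
reported against the simulated 2.5%/50%/97.5% quantiles per degree.
The companion tests verify the two directions that matter: a
well-specified model keeps the observed curve inside the envelope, and
data generated with strong sociality heterogeneity ($\sigma_a = 2$)
but refitted with $\alpha \equiv 0$ pushes the observed tail outside
it.

## Clustering and network organisation

Nodes are grouped by structural equivalence: the Euclidean distance
matrix between posterior-mean socialities is clustered by
complete-linkage agglomeration (`complete_linkage()`, with merge
heights checked against a brute-force $O(n^3)$ oracle in the tests)
and cut into $k$ groups (default 5, a flag rather than an automatic
choice). Distances are computed on posterior means — the scalar
summary the node ranking is based on — rather than on full posterior
vectors; with scalar socialities the mean is the natural clustering
coordinate. Cluster labels are renumbered so cluster 1 has the highest
mean sociality, and `cluster_report()` emits the Table-style summary
(size, degree range per cluster) plus the flow matrix: the percentage
of all network edges running within and between clusters, which sums
to 100 and abstracts the network's organisation away from individual
nodes.

## The synthetic-data generator

The real high-confidence Y2H protein interaction map the method was
designed around is not redistributable, so `generate_synthetic_study()`
draws study data from the model's own generative law:
$g_i \sim \mathrm{Bernoulli}(p)$, $a_i \sim N(0, \sigma_a^2)$,
$\alpha_i = \gamma g_i + a_i$, then Bernoulli edges. Its defaults are
fixed at the scale of that map: $n = 401$ nodes, $\theta = -5.68$,
$\gamma = 0.06$, covariate prevalence $0.32$ (130 of 401 disordered at
the 0.7 probability threshold). $\sigma_a = 1$ is the one free choice:
published sociality estimates for such networks span roughly 0 to 3.5
on the logit scale with heavy residual effects, and a unit-variance
random effect reproduces that spread. These are the study conditions,
not tuning knobs.

What the generator emulates is the statistical structure the analysis
assumes — dyadic independence given socialities, a single binary
covariate, normal random effects. Real interaction maps violate all
three in places (spoke-model sampling artifacts, correlated false
negatives, degree-dependent ascertainment), so passing tests
demonstrate that the machinery recovers what it models, not that the
model is true of any particular dataset.

## Numerical and degenerate-input conventions

* Disorder probabilities binarize inclusively ($\ge$ threshold), with
  the boundary case tested.
* Duplicate edge lines are deduplicated with a warning (`strict = TRUE`
  upgrades to an error); self-loops are always errors naming the line.
* Isolated nodes exist only when declared via an explicit node list —
  an edge list alone cannot represent them, and silently unioning the
  covariate table's IDs into the node universe would mask mismatches.
* Precisions must be strictly positive; a zero-variance chain is a
  "degenerate chain" error in the diagnostics rather than an `Inf`.
* Complete-linkage ties (exactly equal inter-cluster distances) follow
  the deterministic order of the underlying agglomeration; random
  fixtures in the tests have distinct distances with probability one.

## Known limitations

* Dyadic independence given socialities: no triangle/transitivity
  terms, so clustering coefficients beyond what degree heterogeneity
  induces are not captured.
* $\theta$ and the mean random effect are softly identified through the
  prior only; very small or very dense networks widen the $\theta$
  posterior accordingly.
* The goodness-of-fit check covers the degree statistic only; other
  statistics would need their own summaries over the same simulated
  networks.
* Directed networks are supported at the closed-form dyad level, not by
  the sampler; the correlated sender/receiver random-effects extension
  is out of scope.
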