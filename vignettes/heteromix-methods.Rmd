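---
title: "Mixture models for heterogeneous data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture models for heterogeneous data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heteromix)
```

## The model

heteromix clusters N samples $x_i = (x_{i1}, \dots, x_{ip})$ of mixed
discrete and continuous features with a K-component finite mixture

$$P(x_i \mid \Theta) = \sum_{k=1}^{K} \pi_k \, P(x_i \mid \theta_k),
\qquad \pi_k \ge 0,\ \textstyle\sum_k \pi_k = 1,$$

in which each component is identified with one cluster.  In the base
model every component is a naive-Bayes product,

$$P(x_i \mid \theta_k) = \prod_{j=1}^{p} P(x_{ij} \mid \theta_{kj}),$$

with per-feature factors that are Gaussian, categorical over a finite
alphabet, or exponential.  The product form is what allows discrete
sequence positions, expression values and waiting-time-like measurements
to coexist in one model: each feature contributes an independent factor
on its own scale.

Estimation is by expectation maximization.  The E-step computes the
component-membership posterior (the *responsibility*)

$$r_{ik} = \frac{\pi_k P(x_i \mid \theta_k)}
                {\sum_m \pi_m P(x_i \mid \theta_m)},$$

and the M-step replaces $\pi_k$ by the mean responsibility and every
$\theta_{kj}$ by its responsibility-weighted maximum-likelihood estimate.
Iterating the two steps never decreases the observed log likelihood;
`em()` records the per-iteration log likelihood so this guarantee is
checkable, and the test suite asserts it (to `1e-8`) across all component
families.  Because EM only finds local maxima, `rand_max_em()` repeats
the run from seeded random starting points — responsibilities drawn from
a symmetric Dirichlet followed by one M-step — and keeps the best final
likelihood.  Cluster labels are the posterior argmax; `classify()` can
leave a sample unassigned when its posterior entropy, normalized by
$\log K$ so that one cutoff is comparable across K, exceeds a threshold.

## Missing values

A dataset carries a single missing-value sentinel (`"?"` in tables, `"-"`
in sequences by default).  A missing entry contributes the constant
factor 1 to any likelihood (log-contribution 0) and is excluded from
every M-step sum — the standard marginal-likelihood treatment when
missingness is ignorable.  A consequence used by the tests: appending an
entirely missing feature changes no posterior.

## Context-specific independence (CSI)

A conventional mixture gives every component its own parameter set for
every feature.  Often the regularities in data are coarser: for some
feature, several clusters behave identically.  A CSI structure makes
this explicit by partitioning, per feature, the K components into blocks
that share one parameter set.  All-singleton blocks recover the
conventional mixture; one block per feature collapses to a single
naive-Bayes model.  Sharing reduces the free-parameter count (more
robust estimates) and the learned structure itself is interpretable: the
features that keep separate blocks are the ones that discriminate
between clusters.  Components that share every block define identical
densities; `merge_redundant_components()` collapses them, summing their
mixture weights, so structure learning doubles as an automatic reduction
of K.

`structural_em()` interleaves structure search with EM.  Each search
round starts per feature from all-singleton blocks and greedily merges
the pair of blocks with the best score improvement until none improves
(agglomerative search; exhaustive partition search is a Bell-number
blowup).  Ties break toward the merge involving the lowest component
index, making the search deterministic given the responsibilities.

Two design choices here deserve their rationale:

* **The score.**  Candidate structures are compared by the BIC-penalized
  *observed* log likelihood: block parameters are refit by
  responsibility-weighted maximum likelihood, and the candidate's score
  is the resulting mixture log likelihood minus `penalty_weight` (default
  $\tfrac12 \log N$) per free parameter.  The alternative — scoring the
  responsibility-weighted expected complete-data likelihood — looks
  natural but fails a basic sanity check: when K components are fit to
  data from a *single* regime, EM carves the regime into pieces, the
  carved responsibilities make every split look profitable under the
  complete-data score, and the structure never merges.  Under the
  observed-likelihood score such splits barely improve the marginal fit
  and are pruned by the penalty, while genuinely distinct blocks survive
  (the planted-structure test recovers a K=5, p=4 sharing pattern in
  19/20 seeds).  A further benefit: because accepted moves improve the
  penalized observed likelihood *directly*, the trace recorded by
  `structural_em()` (observed log likelihood minus the penalty) is
  monotone by construction rather than via the EM bound.
* **The burn-in.**  The first `burn_in` iterations (default 10) run
  plain EM before any structural move.  A full merge of two components
  is irreversible — once their parameters coincide they receive
  identical responsibilities forever — so the search must not run while
  EM is still pulling components apart.  With a burn-in of 3 the planted
  K=5 structure above is recovered in 15% of seeds; with 10, in all of
  them.  The search then runs every `structure_every`-th iteration
  (default 1).

## Dependence trees

The naive-Bayes assumption can be relaxed to first-order dependencies: a
dependence-tree component assigns each feature one parent and factorizes

$$P(x) = P(x_{\text{root}}) \prod_{j \ne \text{root}}
          P(x_j \mid x_{\mathrm{pa}(j)}),$$

with conditional tables for discrete features and conditional Gaussians
(child mean linear in the parent value) for continuous ones.  A
conditional-Gaussian tree is a constrained parameterization of a
multivariate normal: $3p - 1$ parameters, linear in p like a diagonal
covariance, yet modeling one dependency per feature.

The maximum-likelihood topology is the classical Chow–Liu tree: the
maximum-weight spanning tree of the pairwise mutual-information graph.
Discrete MI is the plug-in estimate from weighted joint frequencies;
continuous MI uses the Gaussian closed form $-\tfrac12\log(1-\rho^2)$ on
the weighted correlation, which is exactly the quantity whose sum the
conditional-Gaussian tree likelihood maximizes (a nonparametric MI
estimate would optimize a different criterion than the model fits).
Mixed discrete/continuous edges are not supported.  The spanning tree is
found by Kruskal's algorithm with edges ordered by decreasing weight and
lexicographic tie-breaking, so the edge set is deterministic; the tests
verify optimality against exhaustive enumeration of all labelled trees
(via Prüfer sequences) for $p \le 5$.  The tree is directed by choosing
a root (feature 1 by default) and orienting away from it; the joint
density is invariant to that choice when conditionals are refit, which
the tests check, so the root is presentation only.

In a tree mixture (`em_dtree_mixture()`, or `em()` on a `dtree_mixture`)
the M-step re-runs the full Chow–Liu fit per component under that
component's responsibilities, so each cluster gets its own topology and
topologies may change between iterations.  Since topology and parameters
jointly maximize the expected complete-data likelihood, the EM
monotonicity guarantee carries over.  For stability-sensitive uses the
topology can be frozen after a chosen iteration.  Rows with a missing
child or parent simply drop that factor; exact marginalization over
missing interior values is left as an extension.

## Semi-supervised estimation

Prior knowledge enters in two forms.  *Hard labels* for a subset of
samples: `labeled_em()` clamps each labelled sample's responsibility row
to its label's indicator and otherwise runs standard EM; with every
sample labelled, one M-step yields the supervised per-class MLE.  The
traced objective (observed likelihood of unlabelled rows plus
complete-data likelihood of labelled rows) is monotone.

*Soft pairwise constraints*: symmetric weights $w^+_{ij}, w^-_{ij} \in
[0,1]$ express a preference that samples i and j should (or should not)
co-cluster, with violation penalties $\lambda^+, \lambda^-$.  The
posterior assignment rule is exponentially tilted by the expected
violation mass against the previous iteration's responsibilities:

$$r_{ik} \propto \pi_k P(x_i \mid \theta_k)\,
  e^{-\lambda^+ \sum_j w^+_{ij} (1 - r_{jk})}\,
  e^{-\lambda^- \sum_j w^-_{ij} r_{jk}}.$$

With empty constraints (or zero penalties) this reduces exactly to the
standard E-step, and binary non-overlapping constraints with
$\lambda \to \infty$ reproduce hard labels; both limits are tested.
One numerical caveat drove an implementation choice: updating all rows
*simultaneously* from the previous responsibilities oscillates with
period 2 under strong positive coupling (two positively-tied samples
keep swapping components), and damping the iteration merely stabilizes a
spurious near-uniform fixed point.  `constrained_em()` therefore sweeps
the update sequentially, row by row against the current values of all
other rows — the coordinate-wise version of the same rule — which on the
two-point instance converges to the co-assignment found by exhaustive
minimization of the penalized objective.  Convergence is monitored on
the penalized objective (likelihood minus expected violation mass), as
the raw likelihood need not be monotone under constraints.  Mixture
weights are re-estimated from the constrained responsibilities like any
M-step.

## Numerical choices

* All densities are computed and accumulated in log space; with hundreds
  of features the linear-scale product underflows.
* Fitted Gaussian (and conditional-Gaussian) standard deviations are
  floored at `1e-6` to prevent component collapse onto a point.
* Discrete fits take an additive pseudocount per symbol, **default 0**
  (pure weighted maximum likelihood).  A nonzero pseudocount turns the
  M-step into a penalized update, which voids the exact EM monotonicity
  guarantee, the exactness of the supervised-MLE limit, and the
  optimality statement behind Chow–Liu structure estimation — the three
  properties the test suite pins down.  With soft responsibilities every
  symbol present in the data gets positive weight in every component, so
  zeros arise only for symbols absent from a column (which are then
  never evaluated).  For hard-label fits on sparse alphabets a
  pseudocount of e.g. `0.1` is recommended and available everywhere
  (`em_settings(pseudocount = )`).
* A component (or CSI block) whose responsibility mass falls below
  `1e-10 * N` keeps its previous parameters for that iteration, with a
  warning, rather than dividing by ~0.
* Argmax ties in classification break toward the lowest component
  index; structure-search and spanning-tree ties break toward the lowest
  indices.  Every stochastic routine takes a seed; repeated runs of the
  command-line pipeline are byte-identical.
* Convergence is declared on the absolute change of the traced
  objective; the first iteration never triggers it.

## The synthetic-data generator

`sample_dataset()` draws component memberships from $\pi$ and features
from the chosen component — exactly the generative process the mixture
assumes, including CSI-resolved parameters and ancestral sampling along
tree topologies.  All parameter-recovery results in the tests and the
acceptance script use it under fixed study conditions: the
two-component Gaussian benchmark (means $\pm 3$, unit variances,
$\pi = (0.4, 0.6)$, $n = 1000$, five restarts), the planted CSI instance
(K = 5, p = 4, block means separated by 4 standard deviations,
$n = 2000$), planted tree mixtures ($n \approx 2000$), and overlapping
clusters at separation $2\sigma$ for the constrained-EM comparisons.
Smaller sizes ($n = 150$, 12 iterations) are used for the 52-trace
monotonicity sweep, where the property holds at any size.

What the generator does *not* emulate bounds what passing tests show:
real data contain outliers, heavy tails, dependent features that no
tree captures, non-ignorable missingness and label noise in the
constraints, none of which are present in model-faithful draws.  The
recovery results certify the estimators on data from their own model
class; robustness claims beyond that require real-data benchmarks.

## Known limitations

* Feature-relevance ranking (`rank_features()`) is defined for product
  and CSI mixtures, whose per-feature marginals are model parameters; it
  raises an error for tree mixtures.
* Mixed-type tree edges, full-covariance Gaussian components, and
  Dirichlet priors beyond the pseudocount are out of scope, as are HMM
  components.
* Sequences must be of equal length (one feature per position);
  unaligned input is rejected rather than padded.
* Constraint matrices are dense N×N; the sequential sweep is
  O(N · K · p + N² K) per iteration, comfortable for hundreds of samples
  but not for tens of thousands of constrained points.
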