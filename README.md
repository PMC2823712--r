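# heteromix

Finite mixture models for clustering heterogeneous biological data in R.

Exploratory analysis of biological data — fixed-length DNA/protein
sequences, expression profiles, phenotype tables — usually starts by
finding groups of mutually similar samples.  Such data are noisy,
high-dimensional, mix discrete and continuous measurements, and contain
missing values, which makes hard partitioning (k-means, hierarchical
cuts) brittle.  heteromix implements model-based clustering with finite
mixtures for exactly this setting, for analysts who want probabilistic
cluster memberships, principled missing-data handling, and models whose
structure is itself interpretable.

## The models

A K-component mixture

> P(x | Θ) = Σₖ πₖ P(x | θₖ)

identifies each component with one cluster.  Estimation is by
expectation maximization (EM): the E-step computes the membership
posterior r₍ᵢₖ₎ = πₖ P(xᵢ|θₖ) / Σₘ πₘ P(xᵢ|θₘ), the M-step refits all
parameters by responsibility-weighted maximum likelihood; the log
likelihood never decreases.  On top of the base naive-Bayes model
(per-feature Gaussian, discrete or exponential factors, so discrete and
continuous features mix freely) the package provides:

* **CSI mixtures** (`structural_em()`): per feature, components may
  share one parameter set; the sharing structure is learned by
  structural EM with a BIC-penalized score, exposes which features
  discriminate which clusters, and components that share everything are
  merged — an automatic reduction of K.
* **Mixtures of dependence trees** (`em_dtree_mixture()`): each
  component is a directed-tree factorization P(x_root)·Π P(xⱼ|x_pa(j))
  whose topology is re-estimated per component at every EM iteration as
  the maximum-weight spanning tree of the mutual-information graph
  (Chow–Liu), with conditional Gaussians or conditional tables on the
  edges.
* **Semi-supervised estimation**: partial hard labels
  (`labeled_em()`) or soft pairwise must-link / must-not-link
  constraints with penalty weights λ⁺, λ⁻ (`constrained_em()`); hard
  labels are the binary, infinite-penalty special case.

Supporting machinery: FASTA ingestion (one discrete feature per
position), typed delimited tables with missing-value markers, a
model sampler for simulation studies, posterior classification with a
normalized-entropy cutoff, feature-relevance ranking, JSON model
serialization, and a command-line interface.  See
`vignettes/heteromix-methods.Rmd` for the methods and design decisions.

## A worked example

Cluster ten synthetic DNA 10-mers drawn from a two-component positional
model (component 1 A-rich, component 2 T-rich):

```r
library(heteromix)

truth <- mixture_model(c(0.5, 0.5), list(
  product_component(lapply(1:10, function(j)
    dist_discrete(c("A","C","G","T"), c(0.85, 0.05, 0.05, 0.05)))),
  product_component(lapply(1:10, function(j)
    dist_discrete(c("A","C","G","T"), c(0.05, 0.05, 0.05, 0.85))))))
write_model(truth, "truth.json", feature_names = paste0("pos", 1:10))
run_simulate("truth.json", 10, seed = 4, out_prefix = "toy")

data <- read_fasta("toy.fa")
data
#> <mix_dataset> 10 samples x 10 features (10 discrete, 0 continuous)

fit <- rand_max_em(build_template(data, K = 2), data,
                   em_settings(seed = 2, max_iter = 40, tol = 0.1,
                               n_restarts = 3, pseudocount = 0.1),
                   verbose = TRUE)
#> Step 1: log likelihood: -96.27848833 (diff = 1)
#> Step 2: log likelihood: -88.73695731 (diff = 7.541531021)
#> Step 3: log likelihood: -64.56562918 (diff = 24.17132813)
#> Step 4: log likelihood: -55.39710362 (diff = 9.168525561)
#> Step 5: log likelihood: -55.39136322 (diff = 0.005740396499)
#> ...                                   (three seeded restarts)

classify(fit$model, data, entropy_cutoff = 0.9)
#> ** Clustering **
#> Cluster 0, size 5
#>   s1, s5, s7, s8, s9
#> Cluster 1, size 5
#>   s2, s3, s4, s6, s10
#> Unassigned due to entropy cutoff: 0

head(rank_features(fit$model, data), 3)
#>   feature    score
#> 1    pos4 1.820290
#> 2    pos3 1.708857
#> 3    pos9 1.708857
```

The per-step lines show the monotone EM log likelihood (the step-1
`diff` is against a dummy baseline); all three restarts converge to the
same optimum, −55.39.  The clustering recovers the two planted groups
exactly; no sample exceeds the entropy cutoff, so none is left
unassigned.  The feature ranking reports each position's
mixture-weighted symmetrized Kullback–Leibler divergence between the
fitted component marginals — here every position is informative by
construction, and the least informative ones simply drew the most
overlapping samples.

The same pipeline runs from the shell (see
`system.file("exec", "heteromix", package = "heteromix")`):

```sh
heteromix simulate --model truth.json --n 10 --seed 4 --out toy
heteromix cluster  --input toy.fa --out run --K 2 --seed 2 \
                   --tol 0.1 --restarts 3 --pseudocount 0.1
heteromix classify --model run.model.json --input toy.fa --out pred
```

`cluster` writes the fitted model (`run.model.json`), the clustering
with posteriors (`run.clustering.tsv`, 0-based labels, `NA` for
entropy-gated samples), the per-iteration log likelihood
(`run.loglik.tsv`), a structure report (CSI block table or per-component
tree edge lists), a feature ranking, and the run configuration with its
seed; repeated runs with one seed are byte-identical.

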