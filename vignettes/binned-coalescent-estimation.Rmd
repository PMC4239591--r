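---
title: "Binned coalescent-based species tree estimation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binned coalescent-based species tree estimation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `bbca`, the numerical
choices made in the implementation, and the assumptions a user should check
before trusting the output. Code chunks are illustrative and not evaluated
when the vignette is built; the worked example in the README is a complete
runnable session.

## The multispecies coalescent

A *species tree* describes the divergence history of a set of species; a
*gene tree* describes the genealogy of one locus sampled from those
species. The two need not agree: when an internal branch of the species
tree is short relative to the population size, lineages entering that
branch may fail to coalesce within it and instead coalesce deeper in the
tree, possibly in an order that contradicts the species tree. This is
incomplete lineage sorting (ILS), and the multispecies coalescent (MSC) is
its standard probabilistic model.

`bbca` measures species-tree branches in *coalescent units* (time divided
by population size). Within a branch carrying `k` gene lineages, the
waiting time to the next coalescence is exponential with rate
`k (k − 1) / 2`, each pair equally likely to merge; lineages still distinct
at the top of a branch are passed to its parent, and everything remaining
above the root coalesces in the root's infinite stem. `simulate_gene_trees()`
implements exactly this contained (censored) coalescent, one sampled
lineage per species, and returns ultrametric gene trees in coalescent time
units.

For any three species the MSC gives a closed form that the whole package
revolves around. If `t` is the length (in coalescent units) of the
species-tree path between the most recent common ancestor of the triple and
the more recent ancestor of its closest pair, then a random gene tree
resolves the triple

- like the species tree with probability `1 − (2/3) e^{−t}`, and
- each of the two other ways with probability `(1/3) e^{−t}`.

At `t = 0` all three resolutions are equally likely; as `t → ∞` the match
probability approaches 1.

## The pseudo-likelihood estimator

`tabulate_triplets()` counts, for every 3-subset of taxa, how many input
gene trees resolve it each of the three ways (unresolved triples are
skipped; taxa may be missing from individual gene trees). The estimator
`mpest()` maximizes the *pseudo-likelihood*: the product over triples of
multinomial likelihoods under the closed form above, treated as if the
triples were independent. They are not independent — that is what makes
this a pseudo-likelihood — but maximizing it is a statistically consistent
way to recover the rooted species-tree topology, and it only requires
rooted gene-tree topologies, not branch lengths or alignments.

Numerical choices:

- Triplet probabilities are floored at `1e-12` before taking logs, so a
  single discordant gene tree cannot produce `−Inf`.
- Internal branch lengths are optimized by coordinate ascent over branches
  (convergence tolerance `1e-6` on the objective), each one-dimensional
  step solved by `stats::optimize()` (tolerance `1e-8`) on the interval
  `[0, 20]` with both endpoints checked explicitly. Twenty coalescent units
  is "effectively infinite": the mismatch probability at `t = 20` is below
  `10^{-9}`, so the bound only shows up when the data contain essentially
  no discordance for a branch.
- For a single triple with match fraction `f` the MLE is closed-form:
  `t̂ = −ln((3/2)(1 − f))` when `f > 1/3`, else `0`. The optimizer
  reproduces this to 4 decimals, which serves as its unit-level oracle.
- Terminal branch lengths are not identifiable from triplet frequencies and
  are reported as `NA`.
- Topology search is exhaustive for up to 8 species (enumeration of all
  `(2n − 3)!!` rooted binary topologies — 105 at `n = 5`, 135,135 at
  `n = 8`) and best-of-`n_runs` rooted-NNI hill-climbing from random
  starting topologies otherwise. Scores are memoized per canonical
  topology, and ties or restarts are fully determined by the seed.

```{r}
fit <- mpest(gene_trees, n_runs = 10, seed = 1)
summary(fit)
logLik(fit)   # df = number of internal branches
plot(fit)
```

## Why bin the loci?

Bayesian co-estimation of gene trees and the species tree is the most
accurate way to obtain *rooted* per-locus gene trees, but its MCMC scales
poorly in the number of loci: beyond a few dozen loci, chains stall and
effective sample sizes of key statistics stay far below the customary
threshold of 100. The pipeline therefore splits the loci into random bins
(default 25 loci each, `random_partition()`), co-estimates within each bin
where the MCMC is tractable, and hands all resulting per-locus gene trees
to the triplet summary above.

Two properties make this sound:

- The summary step consumes per-locus gene trees only, so once those are
  fixed the estimate does not depend on how loci were grouped. The test
  suite checks this *binning invariance* directly for bin sizes 10, 25, 50
  and 100.
- Bins are seeded independently at partition time, so the pipeline's result
  is identical whether bins are processed sequentially or concurrently, and
  is reproducible from the single master seed (`derive_seed()` maps the
  master seed and a stage label to a sub-seed).

## The within-bin estimator

The built-in step 2 (`surrogate_estimate_bin()`) is a deliberately simple
stand-in for full Bayesian co-estimation: per locus, Jukes–Cantor distances
(`ape::dist.dna`), neighbor joining, outgroup rooting, and a nonparametric
bootstrap over sites whose replicates form the locus's "tree sample"; the
MCC tree of that sample is the point estimate. It is fast, deterministic
given the seed, and adequate for simulation studies and for exercising the
pipeline end to end. It is *not* a substitute for co-estimation on hard
empirical data — distance-based gene trees are noticeably less accurate.
For real analyses, export each bin with `write_external_config()`, run your
Bayesian co-estimation program on the bundle (two chains; the config
records chain seeds, chain length and sampling interval), and re-import the
posterior samples with `read_external_results()`, which removes 50%
burn-in per chain before combining, summarizes each locus by its MCC tree,
and subsamples a fixed number of trees per locus for distribution mode.

In `mode = "point"` each locus contributes one tree to the triplet table;
in `mode = "distribution"` each locus contributes a seeded subsample
(default 100) of its tree sample, so gene-tree uncertainty flattens the
triplet counts instead of being discarded. Counts scale out of the
pseudo-likelihood maximizer, so the two modes agree whenever each locus's
sample is concentrated on its point estimate.

## Convergence diagnostics

`ess()` implements the standard autocorrelation-time estimator:
`ESS = N / (1 + 2 Σ ρ_k)` with the sum truncated at the first negative
sample autocorrelation (initial-positive rule), capped at `N`. On an AR(1)
chain with parameter `ρ` the theoretical value is `N (1 − ρ) / (1 + ρ)`,
which the tests verify at `ρ = 0.9`. `convergence_report()` applies the
threshold-of-100 rule per statistic across runs, and `read_trace_log()`
parses tab-delimited MCMC trace logs with per-chain burn-in removal.

## The simulators

`make_model_condition()` builds two synthetic study designs:

- `"strongILS-like"`: 11 taxa (10 ingroup + outgroup), a short coalescent
  ingroup tree (strong ILS), and strong per-gene heterogeneity in GTR
  exchangeabilities, base frequencies, gamma shape and rate.
- `"laurasiatheria-like"`: 12 taxa, a deeper tree (moderate ILS), milder
  heterogeneity, sequence lengths restricted to 500/1000/1500 sites.

These are *emulations of the shape of such studies* — taxon counts, ILS
levels, heterogeneity structure — not re-implementations of any particular
published dataset; numbers obtained from them characterize this package's
behavior only. Sequences evolve under GTR(+Gamma) with the rate matrix
scaled to one expected substitution per site per unit branch length,
transition probabilities computed by symmetric eigendecomposition, and
discrete gamma rates (4 categories, median quantiles, mean-normalized).
In the Jukes–Cantor limit the mismatch fraction across a branch of length
`t` is `(3/4)(1 − e^{−4t/3})`, which calibrates the simulator in the tests,
and a cross-check against an independent implementation (`phangorn`) runs
when that package is available.

## Assumptions and limitations

- All gene-tree discordance is attributed to ILS: no hybridization, gene
  flow, recombination within loci, or paralogy.
- One haploid sample per species; species-tree branches in coalescent
  units mean per-branch population sizes are absorbed into branch lengths.
- Rooted gene trees are required, hence the mandatory outgroup in step 2.
- Pseudo-likelihood values are comparable across topologies for the same
  gene-tree input but are not true likelihoods; model-selection statistics
  built on `logLik()` should be interpreted accordingly.
- Internal branch estimates above ~5 coalescent units are effectively
  lower bounds (the data contain almost no discordance to measure them),
  and the optimizer caps them at 20.
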