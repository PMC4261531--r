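---
title: "Models and methods in rjtraits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in rjtraits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rjtraits implements a Bayesian comparative analysis of binary
morphological characters on a posterior sample of phylogenetic trees, in
the style of the BayesTraits MULTISTATE/DISCRETE protocols: marginal
ancestral-state reconstruction at designated clades, tests of dependent
(correlated) evolution for character pairs, and a Z-score-based
contingency network that orders character-state changes in time.  The
motivating application is the evolution of leaf masquerade in nymphalid
butterfly wing patterns, where 11 binary characters describe
nymphalid-ground-plan elements of the fore- and hindwing and state 1 is
the dead-leaf condition; nothing in the package is specific to that
system beyond the bundled 11-character codebook
(`character_codebook()`).

## The evolutionary models

A single character evolves on a rooted, branch-length tree as a 2-state
continuous-time Markov chain with gain rate $q_{01}$ and loss rate
$q_{10}$.  A pair of characters evolves as a 4-state chain over the
joint states $(0,0), (0,1), (1,0), (1,1)$ in which the two
"double-change" transitions are structurally zero, so only one character
changes at a time.  The *dependent* model has eight free transition
rates $q_{12}, q_{13}, q_{21}, q_{24}, q_{31}, q_{34}, q_{42}, q_{43}$
(states numbered 1-4 in the order above): each character's gain and
loss rates differ according to the other character's current state.
The *independent* model imposes $q_{12}=q_{34}$, $q_{13}=q_{24}$,
$q_{21}=q_{43}$, $q_{31}=q_{42}$, leaving four free rates; under these
constraints the joint likelihood factorises exactly into the product of
the two single-character likelihoods, a structural identity the test
suite verifies to $10^{-9}$.

Likelihoods are computed by Felsenstein's pruning algorithm (C++ core,
per-node rescaling, spectral matrix exponentials with a
scaling-and-squaring fallback for defective generators and a closed form
for two states).  Polymorphic observations `0/1` enter as partial
likelihoods of 1 for each permitted state, the standard treatment of
ambiguity that gives both resolutions equivalent weight.  The root prior
is uniform over states inside all samplers; a stationary-distribution
root is available for fixed-rate likelihood work
(`root_prior("stationary")`).

## Reversible-jump MCMC over rate models

Rather than sampling rate values alone, the sampler walks the space of
*rate models*: every partition of the named rates into classes sharing
one positive value, with a distinguished (possibly empty) zero bin for
structurally absent transitions.  The model prior is uniform over these
configurations; class values carry either a uniform prior on $(0, 100]$
(the conventional BayesTraits-style bound; configurable) or a gamma
prior whose mean and shape are hyperparameters, each uniform on
$(0, 10]$ and resampled by Metropolis-Hastings within the chain.

The move kernel combines (a) a sliding-window update of one class
value, whose width (`ratedev`) is tuned multiplicatively during burn-in
to a 30% acceptance target and frozen afterwards; (b) split/merge moves
on classes, with the new class value drawn from the rate prior so the
dimension-matching terms cancel; (c) moves of a single rate into or out
of the zero bin; and (d) a uniform resampling of the tree index over
the posterior tree sample, which integrates phylogenetic uncertainty at
the cost of one pruning pass per iteration.  Acceptance ratios are
derived on the quotient space of (partition, per-class values), so the
chain's marginal over configurations is exact; with the likelihood
disabled, the sampler provably recovers the uniform model prior, and
the test suite checks the class-count distribution for the 8-rate model
against exhaustive enumeration of all 21,147 configurations.

Chain settings come in two profiles.  The `"desk"` profile
($10^5$ iterations, $10^3$ burn-in, thinning 10) runs in seconds and is
the package default; all tests and the acceptance script further scale
chain lengths and replicate counts to keep the whole suite in the
minutes range on one core, and state the sizes they use.  The
`"paper"` profile records the published cluster-scale BayesTraits protocol
($5.005 \times 10^7$ iterations, $5 \times 10^4$ burn-in, thinning 1000
for ancestral runs; $5.005 \times 10^8$ iterations for dependence runs)
and is provided for completeness.

## Ancestral states at designated clades

`reconstruct_mrca()` implements the MRCA approach: for every retained
posterior sample (a rate model plus a tree index), the most recent
common ancestor of the clade's taxa is located in that sample's tree --
the minimal node containing all of them, which may subtend extra taxa
when the exact clade is absent, with the fraction of exact-clade trees
reported as `coverage` -- and the marginal state probabilities at that
node are computed by clamped pruning.  The estimate is the average of
these per-sample probabilities (not the probability under averaged
rates; a two-tree hand computation in the tests pins this down).
Labels follow the conventional confidence tiers: the winning state is `strong` at
posterior probability $\ge 0.95$ and `moderate` at $\ge 0.85$ (both
inclusive), otherwise `unresolved`.

## Dependent evolution and the contingency network

For each character pair, dependent and independent models are fitted
with the same trees, prior and settings, each with at least three
independent chains; the marginal likelihood of each chain is estimated
by the harmonic mean of its sampled likelihoods (computed in log space).
Because the harmonic-mean estimator is noisy, runs are combined by the
median, the maximum within-model spread is reported, and a warning is
raised when it exceeds 2 log units.  The decision statistic is

$$\mathrm{log\,BF} = 2\,(\ln \mathrm{HM}_{\text{dep}} -
\ln \mathrm{HM}_{\text{indep}}),$$

with values strictly greater than 2 read as evidence for dependent
evolution.  `all_pairs_scan()` applies this to all unordered pairs (55
for 11 characters), records failures per pair without aborting, and
caches per-pair results so a scan is resumable.  No multiple-comparison
correction is applied across the 55 tests, deliberately mirroring the
BayesTraits-era protocol this package reimplements; users comparing many characters should bear the
raw-scale interpretation in mind.

For pairs flagged dependent, the *Z-score* of each of the eight rates is
the percentage of posterior samples placing that rate in the zero bin --
a high Z-score marks an evolutionarily restricted transition.
Classification compares the critical pairs $q_{12}$ vs $q_{34}$ and
$q_{13}$ vs $q_{24}$ at a 70% threshold: a gain restricted on the empty
background but free on the derived background makes that gain contingent
on the partner character and yields a directed (temporal) edge from the
enabling character's gain to the contingent gain; both asymmetries at
once yield an undirected mutual edge; anything else stays
`dependent-unclassified` rather than being forced into the dichotomy.
Loss-rate restrictions are computed and reported but never generate
edges, because the network's events are gains.  Classification defaults to fits under the gamma hyperprior, as in the
protocol this package reimplements.
Edges carry display tiers (weak $\ge 70$, moderate $\ge 90$, strong
$\ge 95$), nodes are layered by longest-path depth so earlier changes
sit at the top, and any strongly connected component of size above one
is reported rather than silently broken.  Exports: Graphviz DOT (solid
arrows for temporal edges, pen width by tier; dotted `dir=none` lines
for mutual edges), TSV edge lists, and JSON round-trippable with
`read_network_json()`.

## Synthetic data: what it emulates and what it does not

`make_fixture_study()` generates studies with the shape of the
motivating data set: 47 taxa, 11 binary characters, and a tree sample
standing in for a Bayesian posterior.  Trees are pure birth
(`simulate_yule_tree()`, unit speciation rate, expected root-to-tip
depth $\sum_{k=2}^{n} 1/k \approx 3.4$ at 47 taxa); the posterior
sample is emulated by lognormal branch-length jitter with unit mean
(sdlog 0.1), optionally with NNI topology moves.  Characters evolve by
exact event simulation with full event logs, so planted structure can
be audited rather than assumed:

* `"null"`: all characters independent, gain = loss = 0.25 (a handful
  of changes per character across the tree, matching the mixed
  prevalences of real wing characters);
* `"planted-pairs"`: pairs (Ch1, Ch2) and (Ch3, Ch4) share a dependent
  generator with a structural zero ($q_{12}=0$, $q_{34}=2$): Ch2 can
  only be gained on the Ch1 = 1 background;
* `"planted-order"`: Ch1 → Ch2 → Ch3 form a contingent chain in which
  each gain rate is structurally zero until the predecessor is derived.
  The unlocked gain rate is 0.5 and the loss rate 0.1, i.e. one to two
  unlocked gains per root-to-tip path; substantially hotter rates would
  saturate the early characters and leave no empty-background
  observations, which is both unrealistic for a late-gain cascade and
  uninformative about contingency.

For power experiments on Z-score recovery, the test suite and the
acceptance script use the classic correlated-evolution design: a slow,
nearly irreversible background character ($q_{13}=0.2$, $q_{31}=0.05$),
a fast foreground on the derived background ($q_{34}=3$, $q_{43}=1$)
with rapid purging on the empty background ($q_{21}=1$), the planted
zero at $q_{12}$, and the foreground's background-loss path inactive so
transient $(0,1)$ tips cannot contradict the restriction.  Replicates
are drawn on 150-tip trees and conditioned to carry at least 40 tips on
each background: unconditioned pure-birth realisations frequently fix
the background character early, leaving the data with no information
about $q_{12}$ whatsoever, and the experiment is about recovery of a
signal that is present, not about the incidence of informative data
sets.

The generator matches the inference model's assumptions exactly
(background-gated rates, no double transitions), which makes parameter
and edge recovery well-posed tests of the machinery.  It deliberately
does not emulate features of real data such as model misspecification,
correlated characters beyond the planted structure, sampling biases in
taxon selection, or topological error in the tree posterior beyond
branch-length jitter; passing tests therefore validate the
implementation, not the robustness of the method to violations of its
assumptions.

## Numerical and design choices

* Matrix exponentials: closed form for 2 states; otherwise
  eigendecomposition with the factorisation rejected (and
  scaling-and-squaring used) when reconstruction error exceeds
  $10^{-9}$ relative; negative round-off entries clipped at zero.
* Pruning uses per-node rescaling in log space, so 47-taxon likelihoods
  near machine-underflow remain finite.
* The subsample size of the tree posterior is an explicit parameter of
  `subsample_trees()`; no default is imposed because published
  protocols vary in how many trees they retain.
* Unrooted input trees are rejected, not midpoint-rooted: silent rooting
  changes likelihoods.
* Branch lengths are used as-is; `rescale_tree_sample()` offers an
  optional global rescaling (off by default everywhere).
* Ties in `classify_pair()` resolve conservatively: a Z-score exactly at
  the threshold does not count as restricted.
* Stage seeds in `run_full_analysis()` derive deterministically from the
  master seed, and the manifest records every derived seed and setting,
  so any stage can be re-executed in isolation.

## Known limitations

Deep-node ancestral reconstructions of characters with a single
evolutionary origin are intrinsically polarity-ambiguous: an
irreversible-loss explanation (ancestral presence with repeated loss)
competes with the single-gain explanation, and the zero bin gives such
configurations nonzero posterior mass, capping the achievable posterior
probability at ancestral nodes even when the generating process is
known.  This is a property of reversible 2-state models on ultrametric
trees -- maximum-likelihood reconstruction exhibits the same
preference -- and it is why reconstructions in the test suite assert
clear majorities rather than near-certainty for single-origin fixtures.
Real studies resolve the ambiguity with outgroup structure and
homoplasy, which multi-origin fixtures reproduce.

The harmonic-mean marginal-likelihood estimator is known to be unstable;
the package follows the standard protocol (≥ 3 runs, median, spread
reporting) rather than replacing it with stepping-stone or
thermodynamic-integration estimators, which are out of scope by design.
At desk scale the log-BF of a truly independent pair occasionally
exceeds 2; the package reports raw values and leaves the
multiple-testing caveat to the user, as the log-BF > 2 rule itself does.
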