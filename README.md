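# rjtraits

Bayesian comparative analysis of binary morphological characters on a
posterior sample of phylogenetic trees: reversible-jump MCMC over
rate models for single characters and character pairs, marginal
ancestral-state reconstruction at designated clades, harmonic-mean
Bayes-factor tests of dependent evolution, and Z-score contingency
networks that order character-state changes in time.

The package targets the kind of question raised by the evolution of
leaf masquerade in nymphalid butterflies: given ~47 taxa scored for 11
binary wing-pattern characters (nymphalid-ground-plan elements, state 1
= the dead-leaf condition) and a Bayesian sample of trees, which
ancestral nodes already carried each derived state, which characters
evolved in a correlated way, and in what temporal order did the derived
states accumulate?  It is equally usable for any binary-character
matrix over a tree sample.

## Models

* Single characters: 2-state CTMC with gain/loss rates.
* Character pairs: 4-state CTMC over (0,0), (0,1), (1,0), (1,1) with
  double changes forbidden.  The *dependent* model has 8 free rates
  q12, q13, q21, q24, q31, q34, q42, q43; the *independent* model
  imposes q12 = q34, q13 = q24, q21 = q43, q31 = q42 (4 free rates) and
  factorises exactly into the two single-character models.
* The rj-MCMC sampler walks partitions of the rates into shared-value
  classes plus a structural-zero bin, under a uniform or
  gamma-hyperprior rate prior, resampling the tree index to integrate
  phylogenetic uncertainty.
* Dependence is judged by log BF = 2 (ln HM_dep − ln HM_indep) > 2,
  with harmonic means taken per chain and ≥ 3 chains combined by the
  median.  The *Z-score* of a rate is the percentage of posterior
  samples assigning it to the zero bin; comparing the critical pairs
  (q12 vs q34, q13 vs q24) at a 70% threshold classifies each dependent
  pair as temporally contingent (directed edge) or mutually dependent
  (undirected edge), and the edges assemble into a tiered network
  (70/90/95%).

## Worked example

A complete synthetic study with a planted contingency chain
(Ch1 → Ch2 → Ch3), analysed end to end:

```r
library(rjtraits)

fx <- make_fixture_study("planted-order", n_taxa = 100, n_char = 3,
                         n_trees = 1, seed = 1001)
st <- chain_settings(iterations = 3e4, burnin = 3e3, thin = 10, seed = 2001)

fits <- fit_pair("dependent", fx$trees, fx$matrix, c("Ch1", "Ch2"),
                 prior = rate_prior("gamma"), settings = st)
round(z_scores(fits), 1)
#>  q12  q13  q21  q24  q31  q34  q42  q43
#> 84.4  0.2 11.3  5.2  0.0  1.5  6.4  3.7

classify_pair(z_scores(fits), c("Ch1", "Ch2"))[c("kind", "from", "to")]
#> $kind
#> [1] "temporal"
#> $from
#> [1] "Ch1"
#> $to
#> [1] "Ch2"
```

The gain of Ch2 on the Ch1 = 0 background (q12) sits in the zero bin in
84% of sampled rate models, while the same gain on the Ch1 = 1
background (q34) is essentially never zero: Ch2's derived state is
contingent on Ch1's, so the network draws the directed edge
Ch1:0->1 → Ch2:0->1 — exactly the structure the generator planted.

The configuration-driven pipeline wraps the full analysis (ancestral
report, 55-pair scan for 11 characters, Z-score tables, DOT/TSV/JSON
network, manifest of seeds and settings):

```r
cfg <- run_config(fixture_preset = "planted-order", seed = 1)
run_full_analysis(cfg, "out/")
```

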