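---
title: "Markov chain ontology analysis: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov chain ontology analysis: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcoa)
```

## The model

An ontology is a rooted directed acyclic graph of classes with a
direct-parent relation (is-a and part-of edges, the GO hierarchy
convention); its extension is a set of instances, each carrying one or
more direct class annotations, optional directed links to other
instances, and a weight in $[0,1]$. `mcoa()` maps every class and every
instance to a state of a single finite Markov chain and builds an
adjusted transition matrix $P$:

* a class state moves to each of its direct parents with probability
  $(1-\alpha)/|\mathrm{parents}|$;
* an instance state spreads $(1-\alpha)$ uniformly over its direct
  class annotations and its outgoing instance links;
* every state additionally jumps with probability $\alpha$ according to
  a jump vector $J$ that gives a share $\omega$ uniformly to class
  states and $1-\omega$ to instance states in proportion to their
  weights.

With $\alpha > 0$ the chain is ergodic, so $P$ has a unique stationary
distribution $\pi$ ($\pi P = \pi$, the principal left eigenvector).
Restricting $\pi$ to the class states and renormalizing gives the
steady-state class probability $ssp(c)$, and
$ir(c) = -\log_2 ssp(c)$ is the information rank in bits.

The key modelling consequence is that an instance's unit of evidence is
divided among everything it points to. A gene annotated to two sibling
categories contributes half of its (damped) mass to each; a category
reached only through a long chain of parents receives exponentially
discounted mass ($\times(1-\alpha)$ per step); link-receiving instances
accumulate mass that then flows into their categories. This is what
lets the score separate structures that annotation counting ties, which
`challenge_scenario()` demonstrates on six minimal datasets.

## Parameters

| parameter | default | meaning |
|---|---|---|
| $\alpha$ | 0.15 | random-jump probability (PageRank damping $d = 1-\alpha$); also the per-step decay of transferred rank, i.e. the strength of the semantic-distance discount |
| $\omega$ | 0.01 | share of jump mass sent uniformly to class states; acts as a uniform prior over classes, giving unannotated classes a small non-zero $ssp$ |
| $\beta$ | 0.5 | weight of the $\sum_{c} \ln(ssp_{tar}(c)^2/ssp_{ref}(c))$ regularizer in the enrichment objective (0.6 is a reasonable alternative for weighted expression data) |
| $p$, $q$ | 0.95, 0.05 | generative true-positive and false-positive activation rates; fixed by default, or chosen per greedy iteration from a $10\times10$ grid ($p \in [0.5, 0.99]$, $q \in [0.01, 0.5]$) with `estimate_pq = TRUE` |
| $\gamma$ | 1 | size-penalty constant in `mode = "gengo"`, which replaces the $\beta$ term by $-\gamma|C|$; any value small relative to the per-gene log-likelihood gain behaves similarly |
| $\sigma$ | 0.01 | Bonferroni-corrected p-value threshold used by the significant-only scoring mode |

The defaults $\alpha = 0.15$, $\omega = 0.01$ are the configuration
under which all six diagnostic orderings are asserted; $\alpha$
dominates the semantic-distance behaviour ($ssp(\text{only child}) >
ssp(\text{parent})$ for any $\alpha<1$ here), while $\omega$ trades the
uniform class prior against the data distribution — at $\omega = 0$ an
unannotated class keeps a positive $ssp$ only through inflow from
descendants, at $\omega = 1$ the data are ignored entirely.

## Numerical choices

* **Dangling rows.** A root class has no structural out-edges; its
  entire row is set to the jump vector $J$ (the PageRank dangling-node
  convention), which preserves row stochasticity without a special
  normalization.
* **Degenerate jump targets.** When there are no instances, or total
  instance weight is 0, the class share is forced to
  $\omega_{\mathrm{eff}} = 1$ so $J$ stays a probability vector.
  Zero-weight instances keep their states and out-edges but receive no
  jump mass.
* **Solver.** Power iteration on the sparse-plus-rank-one form, L1
  tolerance $10^{-12}$, cap $10^5$ iterations (the spectral gap is at
  least $\alpha$, so convergence takes a few hundred steps at
  $\alpha = 0.15$). A dense eigen-decomposition path exists for small
  chains and is used as a cross-check in the tests; the suite requires
  $L_\infty$ agreement below $10^{-8}$.
* **Determinism.** States are ordered lexicographically (classes, then
  instances); greedy ties are broken toward the candidate with fewer
  materialized annotations, then lexicographically; benchmark rankings
  break p-value ties by class identifier. Each benchmark replicate
  seeds its RNG from `(seed, replicate)`.
* **Greedy search.** Starts from the empty set, adds the candidate with
  the largest objective gain while the gain exceeds
  $\varepsilon = 10^{-9}$. Candidates are the classes with at least one
  materialized target annotation — other classes cannot explain an
  active gene and have vanishing $ssp_{tar}$. Inside the search,
  $\ln 0$ is clamped to a large negative finite value so that the
  degenerate rates $p = 1$ or $q = 0$ still rank improvements; the
  user-facing `objective()` keeps the exact $-\infty$ sentinel.
* **Correction scope.** For the generative methods, Bonferroni
  correction uses $m = |C^*|$, the size of the selected set — only
  those hypotheses are ever tested. The baseline corrects over all
  classes tested.

## Open design points and the choices made

* **Pair vs per-gene counting of $S_g$/$S_n$.** The objective's
  inactive-gene terms are counted as materialized (instance, class)
  annotation pairs by default; a per-gene variant (each inactive gene
  counted once, toward $S_g$ if covered by $C$) is available as
  `count_mode = "genes"`. The pair convention reads the objective's
  definition of "annotations between inactive instances and active
  classes" literally; both are exposed because the per-gene convention
  matches the original greedy formulation.
* **Target steady states.** $ssp_{tar}$ is computed on a chain built
  from the target instances only (with their weights). The alternative
  — all instances with non-target weights zeroed — changes little here
  because zero-weight instances receive no jump mass; target-only is
  cheaper and is the default.
* **Non-hierarchical class relations** (e.g. regulates) are not added
  to the transition matrix: the model defines no transition term for
  them. They are simply ignored at OBO parse time unless listed in
  `hierarchy_relations`.
* **GO namespaces.** All namespaces are kept in one graph (multiple
  roots are allowed); `filter_namespace()` restricts to one aspect when
  a single-namespace analysis is wanted.
* **$p, q$ in the benchmark.** The simulated methods run with the same
  fixed rates that generated the data, the usual convention when
  benchmarking generative enrichment methods; grid estimation remains
  available.
* **Planted-set size.** The number of active categories per replicate
  is drawn uniformly from $\{1,\dots,n_{active}\}$ (`fixed_size = TRUE`
  plants exactly $n_{active}$), and planted sets are antichains — no
  member an ancestor of another — drawn by sequential rejection from
  the categories with at least `min_direct = 5` *direct* annotations.
  Direct-annotation filtering is used because filtering on total
  (materialized) annotations disproportionately removes leaf
  categories; `annotation_filter_stats()` quantifies this on any
  dataset.

## What the simulation emulates — and what it does not

`random_fixture()` grows a connected rooted DAG by topological parent
sampling (each class draws 1–2 parents among earlier classes) and
annotates each instance to 1–3 uniform classes. `generate_gene_list()`
then implements the generative model itself: genes covered by a planted
category are activated with probability $p$, all others with
probability $q$. The scaled benchmark in the tests and the acceptance
script uses 200 classes, 1000 instances and 50 replicates at $q = 0.1$,
$1-p = 0.25$, $\beta = 0.5$ — sizes chosen so the whole suite runs in
well under a minute while the mean-average-precision ordering between
methods is stable across seeds.

This captures class overlap and semantic distance, the two challenges
a planted-category benchmark can exercise, but real GO annotation
corpora differ in ways the generator does not reproduce: annotation
counts are heavy-tailed (a few huge categories, many singletons),
depth and branching are far more skewed, annotations are correlated
through curation practice, and real gene lists violate the
independent-activation assumption. Passing the benchmark therefore
shows the machinery is correct and that steady-state regularization
helps under the generative model; it does not by itself calibrate
performance on a particular organism's annotations. A small caveat the
noiseless regime exposes: a planted category can be *aliased* by
another class with an identical materialized instance set (e.g. a
parent whose only evidence flows through that child), in which case no
method can distinguish them and average precision dips below 1 even
without noise.

## Limitations

* Computational cost is higher than one-at-a-time tests: every
  enrichment call solves two stationary distributions (reference and
  target) plus a greedy search, though all steps are sparse and the
  reference solution can be reused across targets.
* The greedy search has no optimality guarantee; the tests verify it
  matches exhaustive subset search on small candidate pools, but on
  large ontologies it inherits the usual local-search caveats.
* Results are sensitive to $p$ and $q$: overly optimistic rates can
  substantially change how many categories optimize the objective.
* Class weights and weighted class–class or annotation edges are not
  modelled; only instance weights and unweighted structural edges enter
  the transition matrix.
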