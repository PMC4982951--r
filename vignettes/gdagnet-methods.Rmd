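---
title: "Methods: genome-anchored causal network learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-anchored causal network learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdagnet)
```

## The problem and the model

Serum metabolite panels are heavily intercorrelated, and observational
correlation cannot say whether metabolite A regulates B, B regulates A, or
a third factor drives both. `gdagnet` resolves directionality with
Mendelian randomization applied at genome scale: genotype belongs to a
deeper biological granularity than phenotype, so any edge between a
genetic instrument and a trait has a known direction, and that exogenous
anchoring propagates through constraint-based structure learning to orient
trait–trait edges.

Traits are assumed to follow a linear-Gaussian structural equation model
(SEM) over an unknown DAG: each trait is a weighted sum of its parent
traits, standardized genotype dosages with direct effects, and independent
Gaussian noise. The CI tests are partial-correlation (Fisher-z) tests, so
the method assumes (approximately) multivariate-normal traits after
normalization, linear relationships, causal sufficiency given the measured
set, and faithfulness of the distribution to the generating DAG.
Metabolite abundances are typically skewed; the pipeline therefore offers
a rank-based inverse normal transform (`int_transform()`, Blom offsets),
off by default because the simulator already emits Gaussian traits.

## Genome-wide instruments

Single variants are usually weak instruments. The package instead uses
principal components of the LD-pruned, per-SNP-standardized dosage matrix:
each PC aggregates variation across many loci and no prior knowledge of
variant–metabolite links is needed. This PCA extracts variation *across*
SNPs; it is not the sample-level PCA used for population-stratification
correction, which is out of scope here.

* **LD pruning** (`ld_prune`): greedy left-to-right scan; a SNP is dropped
  when its squared dosage correlation with an already retained SNP within
  a 100-SNP window exceeds `r2_threshold = 0.80`, so each LD clique keeps
  one proxy. Monomorphic SNPs and SNPs with call rate below 95% are
  dropped first (warned), so no correlation is ever computed on a
  zero-variance column.
* **Candidate PCs** (`compute_pcs`): top `k_pcs = 50` components by
  explained variance (capped at the rank bound). Signs are fixed by making
  the largest-magnitude loading positive, so repeated runs and column
  permutations give identical scores.
* **Selection** (`select_instruments`): for each trait, the trait is
  regressed on all candidate PCs and the least significant PC is removed
  until every remaining PC has p < `alpha` (backward elimination,
  `alpha = 0.001`); a PC is an instrument if it survives for at least one
  trait. The published analysis this reconstructs states only the
  significance threshold, not the elimination scheme or the candidate
  count, so both are explicit, documented choices here and both are
  configurable. Selection is deliberately per-trait rather than joint: it
  keeps the procedure well-defined for any number of traits and records
  which traits each instrument is believed to influence.

## Skeleton estimation

`estimate_skeleton` is PC-stable over the joint variable set
{selected instruments ∪ traits}: starting from the complete graph minus
instrument–instrument pairs (genome PCs are orthogonal by construction and
exogenous by design, so edges among them are excluded a priori), an edge
is removed as soon as some conditioning set of neighbours renders the pair
independent at `alpha = 0.001`. Conditioning sets grow from size 0 and, by
default, until no node retains enough neighbours to supply a larger set
(`max_cond = Inf`). A fixed small cap is tempting for speed, but hub
traits make it wrong in a way that matters: a trait with six parents can
require separating sets of size five for its non-neighbours, and capping
at three provably leaves phantom edges even with unlimited data. The
default therefore follows the standard PC schedule; the cap remains
available for exploratory runs on much larger variable sets.

Candidate sets at each size are drawn from the adjacency snapshot taken at
the start of that size, and all node iteration is in sorted name order, so
results do not depend on input column order. With fewer samples than
(conditioning size + 3) the Fisher-z statistic is undefined; such tests
are skipped with a warning.

An oracle mode (`gdag_from_cov`, `n = Inf`) runs the same search against
an analytic covariance matrix, declaring independence when the partial
correlation is numerically zero (tolerance 1e-8). It is used throughout
the tests to separate algorithmic correctness from sampling noise.

## Orientation

Orientation is staged and fully deterministic:

1. **Tier background knowledge.** Every instrument–trait edge is oriented
   instrument → trait before anything else.
2. **Triple classification.** Each unshielded triple a–b–c is classified
   by probing many conditioning sets (subsets of either endpoint's
   neighbourhood up to size two, plus the recorded separating set with and
   without b): *collider* if a and c are separable only without b,
   *definite non-collider* if separable only with b, otherwise
   *ambiguous*. The naive rule — trust the single recorded separating
   set — fails in two characteristic ways at finite n: conditioning on a
   shared child can nearly cancel an open confounding path, recording a
   misleading separating set and flipping the child's true parents; and a
   weak instrument can look marginally independent of its target's
   children, manufacturing false colliders. Under the population oracle
   the classification is exact, because the open two-edge path of a true
   collider keeps the endpoints dependent under *any* set containing b,
   while a chain or fork is blocked *only* by b.
3. **V-structures** are oriented for definite colliders only.
4. **Meek closure.** Rules 1–3 run to a fixed point, with rule 1
   additionally requiring the triple to be a definite non-collider — a
   weak instrument then abstains rather than mis-orienting its target's
   parents. Rule 4 is omitted: with this package's background knowledge
   (root instruments with all edges outgoing) rules 1–3 already orient
   every edge in the reference setting, and anything they leave falls to
   the logged fallback below rather than being silently mis-handled.
5. **Deterministic fallback.** A residual undirected trait–trait edge is
   oriented away from the endpoint adjacent to more instruments, ties
   broken lexicographically by node name; each fallback is recorded, the
   closure is re-run, and a fallback that would close a directed cycle is
   reversed (also recorded).

An orientation demanded in both directions by conflicting rules drops the
edge and logs it; with the conservative triple classification this did not
occur in any fixture run at n = 2479. Every edge carries a provenance tag
(`background`, `v-structure`, `meek`, `fallback`), the output graph is
asserted acyclic on every run, and deleting the instrument nodes
(`trait_subgraph`) leaves the trait network unchanged.

## Network parameters

For the trait network, `network_metrics` reports out-degree, in-degree,
connectivity (their sum — the column identity Σout = Σin = |E| is enforced
by `connectivity_table` when entering published degree counts directly)
and the **maximum effect blocking step**: the number of nodes influenced
along a single path before the effect is blocked, formalized as the length
in edges of the longest directed path from the node, computed by dynamic
programming over a topological order. The edge-count reading is the one
consistent with a sink scoring 0 (nothing downstream is influenced) and
with a node two steps from the nearest chain of sinks scoring exactly 2.
`influence_set` returns strict descendants — the traits an intervention on
the query set could reach.

## Effect estimation

Given the learned DAG, `estimate_effect` regresses the outcome on the
exposure plus a back-door adjustment set and reports the exposure
coefficient with its standard error (per-SD units when traits are
standardized). Two estimands are offered because they answer different
questions:

* `"total"` (default for pairwise queries): adjust for the **parents of
  the exposure**. This blocks every back-door path while leaving all
  directed paths open, so the coefficient aggregates the full causal
  influence — along a chain a→b→c the (a, c) estimate is the product of
  the edge weights.
* `"direct"` (default for the per-edge table): adjust for the **other
  parents of the outcome**, isolating the single-edge structural
  coefficient. These are the fitted SEM weights, which is what
  `simulate()` on a fitted model uses and what should be compared against
  generating weights in recovery benchmarks.

Outcomes that are not descendants of the exposure are flagged structurally
zero (their population effect is exactly zero under the graph) but still
estimated, as a diagnostic. Errors are assumed homoscedastic Gaussian;
robust standard errors are out of scope. Exactly collinear adjustment
covariates abort with an error naming the offending columns.

## The synthetic study and what it does (not) show

`fa_sim_config()` encodes the reference study design: 2,479 samples, 15
traits named after the serum fatty acid metabolites of the motivating
analysis, 29 causal edges, and 320 SNPs in LD blocks of 8. Design choices,
fixed once:

* **Genotypes.** Within a block, SNPs are generated by thresholding
  correlated Gaussian latents (shared-factor correlation
  `within_block_r = 0.9`) at the quantiles of their Hardy–Weinberg dosage
  distribution, so marginals are exactly Binomial(2, MAF) with MAFs
  uniform in [0.1, 0.4] and within-block dosage correlation is tunable;
  blocks are independent.
* **Trait network.** The 29-edge DAG reproduces the published
  per-metabolite out-degree sequence exactly and 13 of 15 in-degrees; the
  two dietary source metabolites (palmitoleate, margarate) have in-degree
  0, a maximum effect blocking step of 5 terminating at laurylcarnitine,
  margarate's influence does not reach myristate, and the two sources
  jointly influence all 13 other traits. The published per-node maxima of
  blocking steps cannot all be realized simultaneously by any DAG (a
  five-step source forces some node to sit at four steps, and none is
  reported there), so the fixture reproduces the degree structure and the
  qualitative propagation claims rather than that full column. Edge
  weights cycle through seven values in 0.27–0.45; unit noise throughout.
* **Genetic effects.** One causal SNP (the first SNP of a distinct block)
  per non-sink trait, with stronger effects (0.5) on the two source
  metabolites than elsewhere (0.3), emulating a study in which some
  metabolites have several significant genome-wide PCs and some have
  none. Instruments on sources alone were verified insufficient to orient
  the full network even with unlimited data — shielded triangles around
  weakly anchored nodes stay in the Markov equivalence class — which is
  why non-sink traits are instrumented; sinks never need instruments
  because their incoming edges orient from upstream.

The generator deliberately omits admixture and population structure,
recombination maps and realistic LD decay, skewed raw abundances,
missingness, and batch effects. Passing recovery tests therefore
demonstrate correctness of the algorithms under the stated SEM
assumptions — not robustness to the full messiness of cohort data, where
instrument strength, normalization, and hidden confounding all bite.

## Numerical choices and determinism

All randomness flows from explicit integer seeds (`sim_config$seed`, the
pipeline master seed); two runs with equal seeds produce byte-identical
artifacts. PC signs, node iteration order, fallback tie-breaks and edge
ordering in outputs are all deterministic. Singular conditioning sets in
the CI test are treated as dependence (the conservative direction).
Zero-variance columns are dropped with warnings, never divided by.

Test-suite problem sizes were chosen to make Monte-Carlo checks sharp but
cheap: structure-recovery curves use 20 replicates at n ∈ {500, 2000,
8000} on the joint instrument+trait system; estimator coverage uses 50
replicates at the design size n = 2479 (1,450 intervals); the
instrument-selection null uses 20 replicates of 15 PCs × 15 traits
(4,500 tests). Monte-Carlo comparisons use 3-standard-error tolerances
computed inside the tests rather than fixed slack.

## Known limitations

* Linearity and Gaussianity are load-bearing: nonlinear regulation or
  heavy-tailed abundances degrade both skeleton and orientation; only the
  marginal inverse-normal transform is provided as mitigation.
* Causal sufficiency is assumed within the trait panel; latent-confounder
  machinery (FCI-style) is out of scope, so unmeasured common causes can
  be absorbed into spurious edges.
* Weak instruments now abstain rather than mis-orient, which means
  sparsely instrumented networks return more fallback-oriented (i.e.
  direction-uncertain, but logged) edges instead of silently wrong ones.
* The learned graph is treated as known when effects are estimated;
  standard errors do not propagate structure uncertainty.
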