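---
title: "Multiscale protein co-expression networks across cancer cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale protein co-expression networks across cancer cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panpronet)
```

## The analysis

`panpronet` models tumor proteomes from several cancer cohorts as a set of
co-expression networks over one shared gene universe and asks three
questions: which proteins are dysregulated in tumors (and which of those
only at the protein level), which co-expression modules recur across cancer
types, and which network nodes are candidate regulators of the dysregulated
signature. The pipeline runs in five stages:

1. **Differential expression (DEP).** Per cohort, a Welch two-sample t-test
   per gene on log-scale values, tumor versus matched normal; effect size is
   the tumor-minus-normal mean difference, and Benjamini–Hochberg FDR is
   taken across tested genes. A gene is a *proteome-specific* DEP when its
   protein FDR is below `q_dep` while its mRNA FDR in the matched
   transcriptome is at least `q_rna`. Cross-cohort recurrence of
   proteome-specific DEPs is scored with an exact multi-set intersection
   test (below).
2. **Network construction.** Per cohort, Spearman correlations between all
   gene pairs on **tumor samples only**, a permutation FDR screen, and a
   planar maximally filtered graph (PMFG): candidate edges are inserted in
   decreasing |rho| order and kept iff the graph stays planar, up to the
   planar bound of 3(n − 2) edges. Planarity is certified by a left–right
   criterion test implemented in C++.
3. **Multiscale modules.** Recursive top-down splitting of each PMFG with a
   resolution parameter alpha; hubs are called against a degree null from
   weight-shuffled PMFGs.
4. **Preservation and communities.** Each module is matched against every
   other cohort's modules (and the matched transcriptome's modules) by
   Fisher's exact test; mutually strongly preserved modules are merged into
   pan-cancer protein interaction communities (PCPICs) with a core protein
   set and a signed community cross-talk network.
5. **Key regulators.** Nodes whose h-step PMFG neighborhoods are enriched
   for the cohort's DEP signatures, aggregated into a pan-cancer ranking
   together with hub status.

## Choices that needed making, and why

### Networks live in the tumor compartment

Correlation screening, module detection, hub calling and PCPIC cross-talk
are computed on tumor samples only. Mixing tumor and normal samples makes
every pair of genes with same-direction tumor shifts correlate — group
separation masquerades as co-expression — and in simulation it fuses all
shifted genes into one "differential" mega-module. Differential expression,
by contrast, uses both compartments by definition.

### Split acceptance: an optimized configuration-model null

Within a parent module we compute shortest-path distances on the PMFG
restricted to the module (edge length = 1 − |rho|), normalize by the parent
diameter, and propose k-way splits (k = 2..4) by k-medoids. Two details
matter:

* **k is chosen by average silhouette width**, not by within-child
  similarity: the latter is monotone in k and always prefers the finest
  split (on a planted two-block graph it happily cuts one block in half).
* **The null must be an optimized null on an unstructured graph.** A split
  found by an optimizer always beats randomly permuted labels, so a
  label-permutation null accepts splits on completely random graphs. We
  instead rewire the parent subgraph preserving its degree sequence, permute
  the edge lengths, and re-run the same k-medoids search on each of
  `n_perm` rewired copies. This keeps the degree structure and weight
  multiset while destroying any real grouping, and it measures what an
  optimizer can achieve on a structureless version of the same parent.

A split is accepted at resolution alpha iff its compactness (mean
within-child similarity) exceeds alpha times the null's 95th percentile and
every child has at least `min_size` members. The ratio of observed
compactness to the null 95th percentile is stored as the split's critical
resolution, clamped by the parent's, so cuts are nested: `modules_at(h, a)`
descends while the critical resolution is at least `a`. Splits are
enumerated at the calibration level alpha = 1 — the 5% permutation test —
so grid values below 1 report the same cut as alpha = 1; larger alpha
demands proportionally stronger separation. The reporting default is
alpha = 1.

In simulation this calibration splits a planted two-clique graph into
exactly the two cliques, leaves PMFGs built from pure-noise weights
unsplit in ≥ 95% of runs, and recovers planted module labels on a
seven-cohort panel with adjusted Rand index above 0.9.

### Preservation calls on the adjusted scale

A module is matched against every module of a target network by the
one-sided hypergeometric (Fisher) test on the universe shared by the two
networks, with BH adjustment across target modules. The best match is
classified `strong` (FDR < `q_strong` and fold enrichment ≥ `fold_min`),
`weak` (FDR < `p_weak`), or `none`. Both thresholds act on the adjusted
scale: with, say, 20 candidate target modules, the chance that some raw p
falls below 0.05 for a random query is far above 5%, and a raw-p weak rule
would label random modules preserved most of the time.

### Mid-p for driver neighborhoods

Driver scoring tests each node's h-step neighborhood against the up- and
down-DEP signatures. Neighborhood-sized overlap tables are small, and the
plain exact tail of a discrete test is markedly super-uniform — its null
p-values cannot pass a uniformity check no matter how the null is sampled.
We therefore use the mid-p variant (half the probability mass of the
observed overlap is counted; zero overlap keeps p = 1), which restores
near-uniform null behavior while leaving decisions on clearly enriched
neighborhoods unchanged. Everywhere else — preservation, community
enrichment — the standard exact tail is used.

### The exact multi-set intersection test

For m sets of sizes n_1..n_m drawn independently and uniformly from a
universe of size n, the intersection size distribution follows by chaining
hypergeometric kernels: conditional on the running intersection having i
elements, its overlap with the next set is Hypergeometric(n, i, n_k). The
reported p is the exact upper tail at the observed intersection; the
expected size is n · prod(n_i / n). For m = 2 this reduces to the Fisher
one-sided tail. The chain is fast at any realistic gene-universe size, so
no Monte-Carlo fallback is needed (a direct sampler exists for testing).

## The synthetic panel generator

`generate_cohort_panel()` emulates the structure of a multi-cancer
proteogenomic study; it is the test bed for every downstream stage.

* **Module signal.** Members of a planted module share one latent factor
  per cohort; gene value = loading × factor + Gaussian noise, loadings
  Uniform(0.6, 1). The same factor drives proteome and transcriptome with
  independent noise (partial concordance). Default noise SD 0.5 on the log
  scale gives within-module correlations around 0.7, typical of tight
  proteomic modules.
* **Regulators.** One member per module gets loading 1 and a quarter of the
  noise; it is the strongest correlate of its module, becomes a high-degree
  PMFG hub, and its neighborhood inherits the module's DEP shift — the
  ground truth for driver recovery.
* **Differential signal.** All members of a module carried by a cohort are
  shifted by ±`dep_effect` (default 2 log-units, one sign per module) in
  tumor samples, plus `n_extra_dep` background genes per cohort; a fraction
  `frac_proteome_specific` (default 0.3) of shifted genes is shifted on the
  proteome only — proteome-specific DEPs by construction.
* **Community cross-talk.** A module may couple its factor to another
  module's (`couple_to`, `couple_rho`). The reference panel couples its
  second pan-cohort module to the first at −0.4. The magnitude matters:
  under absolute-correlation networks two modules whose cross-correlation
  approaches their within-module correlation are a single module — at
  coupling −0.8 with within-module correlations near 0.7 the pair is not
  identifiable as two communities, while −0.4 keeps the cross-module
  correlation below screening strength and still yields a decisively
  negative cross-talk edge (combined p around 1e−6 over seven cohorts).
* **Seeds.** One master seed; each cohort and each stochastic stage consumes
  a stream derived by hashing a stage key with the master seed
  (`derive_seed()`), so runs are bit-reproducible and single stages can be
  re-run in isolation.

What the generator does **not** emulate: batch structure, missingness
patterns, isobaric-labelling ratio compression, peptide-level rollup, and
mutation calls. Passing recovery tests on this generator shows the
machinery is correct and calibrated under its assumptions — latent-factor
modules with Gaussian noise — not that real cohorts meet those assumptions.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `q_dep`, `q_rna` | 0.05 | FDR thresholds for DEP and mRNA-side calls |
| `min_cohorts` | 3 | recurrence threshold for recurrent specific DEPs |
| `fdr_cut` | 0.05 | permutation-FDR cutoff for correlation edges |
| `alphas` | 0.5, 1, 2 | resolution grid; modules reported at alpha = 1 |
| `min_size` | 10 | minimum module size (genes) |
| `n_perm` | 50 | permutations for screen, split null, hub null |
| `hub_q` | 0.05 | null tail defining a hub |
| `q_strong`, `p_weak`, `fold_min` | 0.05, 0.05, 2 | preservation classes |
| `span_min` | all cohorts | cohorts a community must span |
| `core_min` | majority | cohorts a core gene must recur in |
| `p_edge` | 0.05 | combined-p threshold for cross-talk edges |
| `h` | 2 | driver neighborhood depth (edges) |
| `q_driver` | 0.05 | driver FDR threshold |
| `min_neighbors` | 5 | smallest tested neighborhood |

## Numerical and degenerate-input conventions

* Ties everywhere break lexicographically by gene id; PMFG candidates sort
  by weight descending then (gene_a, gene_b), which makes construction
  invariant to input row order.
* Genes with fewer than 3 finite values per group are dropped from DEP
  testing (recorded); constant rows are dropped from screening (recorded).
* A cohort without normal samples yields an explicit no-DEP table and is
  excluded from driver scoring, not an error.
* Zero-variance genes with equal group means get statistic 0 and p = 1.
* Empty query or target sets in enrichment give p = 1 and fold 0.
* An empty community core is retained with a warning.
* Disconnected module parents split into their connected components
  directly; components below `min_size` stay with the parent.

## Problem sizes used by the test suite

The suite exercises the pipeline at desk scale, chosen so the full run
stays in minutes: a reference panel of 7 cohorts x 500 genes (30 tumor /
15 normal samples each) with one pan-cohort module of 40, one
anti-correlated pan-cohort module of 30 and one cohort-specific module of
30; driver recovery on 3-cohort panels of 200 genes over 10 seeds; DEP
calibration on 50 null panels of 1000 genes at 50/50 samples. Results
obtained on full proteogenomic cohorts (thousands of proteins, specific
module counts and hub genes) depend on those data and are not reproduced
at this scale; what is checked is parameter recovery and statistical
calibration of every stage.

## Known limitations

* The PMFG is rebuilt from scratch after each accepted edge during
  construction (O(E · n) overall); networks beyond a few thousand genes
  will be slow.
* Module splitting explores k = 2..4 per level; finer partitions emerge
  through recursion, but a genuinely 5-way flat split is found only as
  nested cuts.
* Preservation is overlap-based (Fisher) by design; correlation-pattern
  preservation statistics (Z-summary style) are out of scope.
* The exact multi-set test assumes sets drawn independently and uniformly
  from the universe — the standard formulation — which is a null, not a
  model of cohort dependence.
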