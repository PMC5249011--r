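---
title: "Spectral consensus network reconstruction: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral consensus network reconstruction: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scsnet)
```

## The problem

Structure learners that work well on a few dozen discrete variables —
mutual-information filters, score-based Bayesian-network search — degrade
badly when asked to reconstruct networks over hundreds or thousands of
variables from comparatively few samples. Microbiome presence/absence
matrices are the motivating case: thousands of co-abundance gene groups
observed across a few hundred subjects, where the scientific object of
interest is the co-presence network among them.

`scsnet` attacks this with a divide-learn-integrate strategy:

1. **Spectral phase.** Variable similarity is measured by pairwise plug-in
   mutual information, giving a weighted graph with matrix $W$. The
   random-walk normalized Laplacian $L_{rw} = I - D^{-1}W$ is decomposed;
   its leading eigenvectors carry community-membership and path-relatedness
   information. For an ideal graph of $c$ disconnected communities the
   eigenvalue 0 has multiplicity $c$ and its eigenvectors are community
   indicator vectors; under perturbation the *magnitude and sign* of the
   elements still rank membership strength. Each of the first $k$
   eigenvectors therefore contributes two overlapping subsets of $m$
   variables: the $m$ most positive and the $m$ most negative elements.
2. **Learn phase.** Every registered learner reconstructs each subset
   locally, where $m \ll n$ keeps it in its comfort zone. A learner's local
   graphs are merged by an *every-time intersection rule*: a pair of
   variables enters the learner's network only if it was recovered in every
   local reconstruction whose subset contained both endpoints. Orientations
   (for learners that produce them) are settled by strict majority over the
   directed local predictions; a tie, or directions only from abstaining
   undirected predictions, leaves the edge undirected.
3. **Consensus phase.** Each learner's edges are ranked by decreasing
   strength and the rank positions normalized to $(0, 1]$ (1 = worst). For
   every pair predicted by at least one learner, missing learners contribute
   the worst possible rank 1, and the consensus score is the unweighted mean
   of the per-learner ranks. The $e_{max}$ best-scoring pairs form the final
   network; orientations are a rank-weighted vote over the orienting
   learners, each casting weight $1 - r + \tfrac{1}{2E_l}$ for its
   direction.

The `scs()` function runs all three phases and returns a classed fit with
`print()`, `summary()` and `plot()` methods.

## Embedded learners

Three learners ship with the package and others plug in through
`register_learner()` (which is also the integration point for external
methods such as hybrid constraint/score learners not reimplemented here):

* **`aracne`** — pairwise MI, a significance threshold, then
  data-processing-inequality pruning: in every triangle the weakest edge
  (by MI, with slack `dpi_tolerance`) is removed, all triangles judged on
  the pre-pruning graph and removals applied simultaneously. Undirected;
  strength = MI.
* **`hc`** — greedy hill climbing over DAGs (add/delete/reverse moves,
  acyclicity enforced) maximizing the decomposable BDeu log marginal
  likelihood. Directed; strength = score drop when the edge is deleted
  from the final DAG.
* **`random`** — keeps each pair with probability `q`, uniform strengths;
  the floor any learner must clear.

## Tunable parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `m` | variables per local reconstruction | user-set | keep $m \ll n$; 12 (5 % of variables) is the benchmark working point |
| `k` | leading eigenvectors used | eigengap heuristic | see below |
| `k_max` | eigengap search cap | $\lceil 0.4\,p \rceil$ | the largest eigenvector proportion explored in the benchmark sweeps |
| `e_max` | consensus edges retained | user-set | the expected edge count of the target network when known |
| `mi_log_base` | MI units | 2 (bits) | units cancel in ranking; bits are conventional |
| `mi_threshold` (aracne) | significance cutoff | permutation null | 100 independent column permutations, 95th percentile of pooled null MI |
| `dpi_tolerance` (aracne) | DPI slack | 0 | strict triangle pruning |
| `equivalent_sample_size` (hc) | BDeu prior strength | 1 | the common uninformative default |
| `restarts` (hc) | greedy restarts | 2 | first from the empty graph, later from random DAGs of expected degree 1 |
| `seed` | root seed | 1 | every stochastic stage draws from the stream this seeds |

**Eigengap heuristic.** The number of informative eigenvectors is chosen
from the ascending eigenvalues $\lambda_1 \le \dots$: with gaps
$g_i = \lambda_{i+1} - \lambda_i$ for $i < k_{max}$, $k$ is the largest
index whose gap reaches half the largest gap; when all gaps are within
10 % of one another no gap is conspicuous and $k = k_{max}$. This concrete
rule is one of several reasonable readings of "choose eigenvectors while
successive eigenvalues are dissimilar enough", and we make no claim it
matches any other implementation; the 0.5 fraction is configurable.
Because the trivial constant eigenvector of a connected graph consumes a
slot but yields no sign structure, `scs()` additionally floors $k$ at
(number of connected components + 1), so at least one informative
eigenvector is always available; the same $k$ is used for every subset
selector so that comparison runs operate on matched subset counts.

## Numerical choices

* Eigendecomposition goes through the symmetric form
  $L_{sym} = I - D^{-1/2} W D^{-1/2}$ (real spectrum guaranteed), mapping
  eigenvectors back via $v_{rw} = D^{-1/2} v_{sym}$. Eigenvector signs are
  fixed by making the largest-magnitude entry positive; subset selection is
  invariant to the choice since both signs are used.
* Zero eigenvalues are detected at relative tolerance $10^{-9}$ of the
  largest eigenvalue.
* Isolated variables (zero MI with everything, hence zero degree) make
  $D^{-1}$ undefined; they are removed before decomposition with a warning
  and can hold no edges.
* Ties everywhere break deterministically: subset selection by ascending
  variable index, tied learner strengths share their mean rank position,
  consensus ties at the $e_{max}$ cut prefer more supporting learners then
  lexicographic pair order, and the ARACNE triangle rule removes the
  lexicographically smallest pair among tied weakest edges.
* The diagonal of $W$ is zero: self-similarity would inflate degrees
  without conveying pairwise information.
* Missing values (a declared missing token in the reader) are dropped
  pairwise per computation: MI uses the complete pairs of its two columns,
  a local learner the complete rows of its $m$ columns.

## Design decisions that were genuinely open

* **Retention strength.** The strength of an edge that survives the
  intersection rule is the arithmetic mean of its local strengths — stable
  under duplicate subsets and scale-free after rank normalization.
* **Orientation abstention.** Undirected local predictions abstain from
  the majority vote rather than forming a third candidate; a tie among
  actual directions already yields an undirected edge.
* **Rank universe.** A learner's normalized ranks divide by its *own*
  edge count, not by all $\binom{p}{2}$ pairs, making the worst predicted
  edge rank exactly 1 — the same value imputed when the learner missed the
  pair entirely.
* **Duplicate subsets** (different eigenvectors selecting the same
  variables) are kept: they add co-inclusion trials, which is what
  "learned every time" asks for; the duplication rate is logged.
* **Misorientation scoring.** A detected pair predicted with the wrong
  direction counts as a false positive; since it is then not a true
  positive, the contradicted true edge is also a false negative, keeping
  recall's denominator at the truth size. Undirected predictions of
  directed truths are *not* penalized. Reported overlap percentages round
  half-up to integers.

## What the synthetic generators emulate — and what they do not

`generate_dag_benchmark()` draws a random DAG at a target average degree,
equips it with Dirichlet(1) conditional tables (dependence strengths from
near-deterministic to negligible) and forward-samples discrete data — the
stand-in for curated Bayesian-network benchmarks. `generate_copresence()`
plants blocks whose members switch on together (latent per-sample Bernoulli
switch, presence probability 0.9 inside an active block vs 0.05
background), emulating the transitive co-presence structure of sparse
microbiome matrices; the truth is the union of within-block cliques.

Neither generator reproduces compositional read-count noise, phylogenetic
correlation between variables, or the heavy-tailed degree distributions of
real ecosystems. Passing the recovery tests therefore demonstrates that the
pipeline recovers planted conditional-dependence and co-presence structure
under the stated noise model — not that it attains any particular accuracy
on real metagenomic data.

## Problem sizes used in the shipped checks

The test suite exercises exact oracles at small scale (brute-force DPI on
up to 6 nodes, exhaustive DAG enumeration at $p \le 4$ — 543 DAGs, all
$2\times2$ Fisher tables with $n \le 12$, spectral invariants on random
block graphs up to $p = 40$) and end-to-end recovery at $p = 60$,
$n = 500$, average degree 3, $m = 12$, $e_{max}$ = the true edge count,
averaged over 5 generated datasets. These sizes were chosen so the whole
suite completes in minutes on a single core while still separating the
selectors clearly; the qualitative ordering (spectral subsets ≫ random
subsets) is stable across seeds at this scale.

On that benchmark the spectral-subset consensus roughly doubles the
F-score of the same learners run on random subsets. The consensus does
*not* reliably exceed the best single embedded learner here: with only two
learners the candidate-pair union barely exceeds $e_{max}$, so rank
averaging and truncation cannot filter weakly-supported pairs, and the
consensus inherits the hill climber's misorientations on pairs the
(undirected, hence unpenalized) ARACNE network also found. A third
complementary learner enlarges the candidate pool and is the regime where
consensus integration pays off; the plug-in registry exists for exactly
that purpose.

## Worked example

```{r example}
bench <- generate_copresence(p = 12, n = 300, n_blocks = 3, seed = 7)
fit <- scs(bench$data, m = 4, e_max = nrow(bench$truth$edges),
           learners = c("aracne", "hc"), seed = 7, truth = bench$truth)
summary(fit)
```

## Known limitations

* Dense $p \times p$ MI matrix and full eigendecomposition: fine to a few
  thousand variables, no sparse/iterative path beyond that.
* The eigengap rule is fragile on spectra without block structure (it may
  collapse to the floor described above).
* The ARACNE permutation null refits per subset; for very large subset
  counts a fixed `mi_threshold` is cheaper.
* Learners assume locally complete data after pairwise dropping; heavy
  missingness will shrink effective sample sizes per subset.
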