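---
title: "Methods: network inference, integration and evaluation in grnkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network inference, integration and evaluation in grnkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnkit)
```

## The problem

Given a matrix of normalized expression values for p genes across n
experimental conditions (microarray or RNA-seq samples), we want a ranked
list of putative regulatory interactions: which regulator influences which
target, and with what confidence. No single inference family dominates
this problem — correlation methods, conditional-dependence methods,
regression methods and constraint-based causal methods all fail in
different regimes — so grnkit implements one representative of each major
family, a rank-aggregation scheme to combine them, and a benchmark
protocol to measure all of them against a known gold standard.

All algorithms consume the same container (a numeric matrix, genes in
rows) and emit the same currency: a ranked edge list, sorted by
descending confidence with a deterministic lexicographic tie-break. Ranks,
not raw scores, are what the downstream integration consumes, which is why
the tie-break is part of the contract: it makes every rank reproducible.

## The six inference algorithms

**Relevance network (RN).** Pairwise Pearson correlation, thresholded.
A pair is kept when $r \ge t_+$ or $r \le t_-$; the default
$(t_+, t_-) = (0.9, -1)$ keeps only strong positive co-expression,
because $r = -1$ is the only value that can pass a negative threshold of
$-1$. The edge score is $|r|$, with the sign retained as metadata — the
ranking uses magnitude, since both strong activation and strong
repression are evidence of regulation, but the sign matters for
interpretation. For rank aggregation and AUC evaluation an `emit_all`
mode scores every pair, leaving truncation to the consumer.

**Graphical Gaussian model (GGM).** Edges are ranked by the magnitude of
the partial correlation between two genes given all others, which removes
indirect correlation mediated by third genes. With genes outnumbering
samples the sample correlation matrix is singular, so the correlation
matrix is shrunk toward the identity with the analytic intensity
$\lambda^* = \sum_{i \ne j}\widehat{\mathrm{Var}}(r_{ij}) / \sum_{i \ne j}
r_{ij}^2$, clipped to $[0,1]$ — the closed-form minimizer of expected
squared loss. For $\lambda^* > 0$ the shrunk matrix is positive definite,
so the inversion never fails. We rank by $|\mathrm{pcor}|$ directly and do
not fit an empirical-Bayes mixture to assign local false discovery rates:
for a two-groups model the local fdr is monotone in $|\mathrm{pcor}|$, so
the ranking — the only thing the downstream ensemble uses — is unchanged.

**CLR.** Mutual information corrected for each gene's background. Raw MI
is biased per gene (high-entropy genes look connected to everything), so
each gene's MI row is converted to z-scores against its own background:
$z_i(j) = \max(0, (\mathrm{MI}_{ij} - \mu_i)/\sigma_i)$, and the pair
score is $\sqrt{z_i(j)^2 + z_j(i)^2}$ — an edge is only strong if it
stands out from *both* contexts. The default MI estimator spreads each
observation over adjacent bins with B-spline basis weights (order 3, 10
bins), which softens the discretization sensitivity of plain histograms;
a closed-form Gaussian estimator ($-\tfrac12\log(1-r^2)$) is offered as a
fast alternative that is exact for normal data. A gene whose background
has zero spread contributes $z = 0$ rather than dividing by zero.

**GENIE3-style tree ensembles.** Each gene in turn is a regression
target predicted from the candidate regulators (TF list minus itself)
with a random forest; a regulator's score is its total variance-reduction
importance. Defaults follow the reference description of the method:
1000 trees, $\sqrt{K}$ candidate features per split. Importances are
normalized per target to sum to one before pooling, so every target
contributes equal mass to the global ranking and high-variance targets
cannot dominate. The forests are fit with the `ranger` library; the
scoring, pooling and determinism contract are grnkit's.

**TIGRESS-style stability selection.** For each target, `n_resamples`
runs each draw half the samples and multiply each regulator's
unit-normalized column by an independent weight uniform on
$[\alpha, 1]$ — the randomized-lasso penalty reweighting — then run
least-angle regression (LARS) for $L$ steps. A regulator's score is its
selection frequency (or, by default, the area under its
selection-frequency curve over steps $1..L$, which is less sensitive to
the choice of $L$). Defaults ($R = 1000$, $\alpha = 0.2$, $L = 5$, area
scoring) follow the method's reference description; around $R = 100$ is
adequate at benchmark scale and is what the test suite uses. The LARS
entry-order routine is implemented in the package because no installed
library exposes it.

**Bounded-order constraint-based learner.** The only method that infers
edge *direction*. It is a constraint-based Bayesian-network structure
learner made tractable for large gene sets by two devices: the
conditioning-set size in conditional-independence tests is capped at
`ord`, and each level's edge deletions are applied synchronously from
neighbourhoods frozen at the start of the level (the "stable" search
order), which makes the output independent of gene ordering and of how
the pair list is partitioned across workers — that property, not a
particular thread library, is the testable meaning of "parallel" here.
CI tests are Fisher-z tests on Gaussian partial correlations: $z =
\tanh^{-1}(r)$, statistic $\sqrt{n - |S| - 3}\,|z|$, two-sided normal
p-value; when $n - |S| - 3 \le 0$ the test is undecidable and the edge is
conservatively retained. After the skeleton search, unshielded triples
$i - k - j$ are oriented as colliders $i \to k \leftarrow j$ exactly when
$k$ is absent from the recorded separating set, and Meek's rules R1–R4
propagate orientations to a fixpoint without creating new colliders or
directed cycles. Conflicting orientation proposals leave the edge
undirected and are counted, never silently resolved. Surviving edges are
ranked by $1 - p_{\max}$, the complement of the largest p-value the pair
ever survived — monotone, bounded, and standard for this family; the
defaults $\alpha = 0.01$, `ord` $= 8$ match common practice for
expression data.

## Rank aggregation and evaluation

**Borda integration.** Each of $K$ lists is truncated to its `top_k`
best edges; every edge in the union is rescored by its average rank
across all $K$ lists, with rank `top_k + 1` charged for absence. For
edges present in all lists this ordering coincides with the
sum-of-ranks formulation; the absence penalty extends it to partial
overlap. When directed and undirected lists are mixed, the composite is
keyed by the unordered pair (a directed list contributes its
better-ranked orientation), and a composite edge is directed only if at
least one supporter directs it and none oppose it.

**AUPR/AUROC.** The evaluable universe is the set of pairs labelled in
the gold standard — unlabelled pairs are ignored, not treated as
negatives, since absence of evidence is not evidence of absence in
curated interaction sets. Predictions are truncated to the top 100,000
edges by default; gold pairs missing from the truncated list complete
the curves under a random-ordering assumption for the remainder (a
linear ROC segment to (1,1) and a closed-form expected
precision–recall tail), so truncation never leaves the metrics
undefined. Areas are trapezoidal. Directionality is scored separately:
skeleton true positives ignore orientation, and among directed
predictions the fraction matching the gold orientation is reported, with
the degenerate all-undirected case flagged rather than divided by zero.

## The synthetic benchmark

The generator draws a known directed network — genes in a fixed
topological order, only TFs with out-edges, so the graph is acyclic by
construction — and simulates steady-state expression from the
linear-Gaussian structural model $x_g = \sum_{p} w_{pg} x_p +
\varepsilon_g$ by ancestral sampling, with standard-normal roots.
Defaults: 50 genes, 20 TFs, 200 samples, mean out-degree 2, weight
magnitudes uniform on $[0.5, 1.5]$ with random sign, noise SD 0.5 —
a regime where regulatory signal is clearly present but far from
noiseless, with effect sizes comparable to the noise scale. The
companion gold standard labels all true edges 1 and all remaining
TF→gene pairs 0 (negatives restricted to pairs a regulator *could* have
reached, mirroring challenge-style evaluable universes).

A linear-Gaussian steady state is a deliberate simplification relative
to kinetic ODE simulators: it preserves exactly the statistical
structure (conditional independences, partial correlations, additive
effects) that every implemented method assumes, while staying
dependency-free and fast. What passing benchmarks therefore shows is
that each method correctly exploits that structure and that the ensemble
and evaluation machinery are sound; it does not certify performance on
saturating kinetics, feedback loops, hidden confounders or heavy-tailed
noise, none of which the generator produces. The closed-form SEM
covariance is exposed (`sem_covariance()`) so exact, sampling-free
analyses are possible.

## Numerical and design choices

- **Tie-breaks.** Equal scores order lexicographically by (regulator,
  target); conditioning-set subsets enumerate in lexicographic gene-ID
  order, smaller frozen neighbourhood first. These affect only which of
  several equivalent witnesses is recorded, never which edges survive.
- **Determinism under parallelism.** Work decomposes per target gene
  (regression methods) or per pair-level (skeleton search); every task's
  RNG stream derives from (seed, target ID) via a fixed polynomial hash,
  so the `workers` knob can never change an output byte.
- **Degenerate inputs.** Zero-variance genes score 0 against all
  partners; constant MI backgrounds yield zero z-scores; singular
  conditioning submatrices fall back to the pseudo-inverse; expression
  rows with missing values are dropped with a logged count, never
  imputed.
- **Score direction.** Larger is always more confident; p-value-native
  methods store $1 - p$.
- **ID handling.** Exact, case-sensitive string matching; an optional
  two-column alias map translates probeset to gene IDs when needed.
- **Ortholog clustering.** Three pairwise reciprocal-best-hit sets are
  merged into metagenes as connected components of the union graph —
  the simplest reproducible rule; components where a species exceeds its
  membership allowance (2 for a designated recently-duplicated genome, 1
  otherwise) are flagged, not silently resolved.
- **Enrichment universe.** The chi-square enrichment universe defaults
  to the analysed gene list (not a whole chip), and the choice is an
  explicit argument; raw p-values are always reported alongside the
  Benjamini–Hochberg column, which is an extension beyond the plain
  chi-square test.

## Problem sizes used by the tests

The test suite and the acceptance script run the benchmark at 50 genes /
20 TFs / 200 samples with 10 and 5 replicate networks respectively, tree
ensembles of 200–500 trees and 100–200 stability-selection resamples,
and a conditioning-set cap of 3 (the generated networks have small
degrees, so deeper conditioning adds tests without changing results).
These sizes were chosen as the smallest at which all six methods
separate cleanly from the shuffled-label control; the package defaults
remain at the reference values (1000 trees, 1000 resamples, `ord` 8).

## Known limitations

- Gaussian CI tests assume roughly linear relationships; strongly
  nonlinear regulation is visible to the tree ensembles and the B-spline
  MI estimator but not to the constraint-based learner or the GGM.
- The bounded-order search can leave truly independent pairs connected
  when the separating set is larger than `ord`; raising `ord` trades
  time for completeness.
- Borda integration treats constituent lists as equally credible; there
  is no learned weighting.
- The orientation phase recovers only what the Markov equivalence class
  determines: edges whose direction is not identifiable from
  observational data stay undirected by design.
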