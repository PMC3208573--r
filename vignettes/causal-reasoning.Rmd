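---
title: "Causal reasoning over signed molecular networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal reasoning over signed molecular networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upcause)
```

## The model

`upcause` infers upstream molecular causes of observed transcriptional
changes from a knowledge base of curated causal statements. A statement
is a signed, evidence-backed edge: an increase of the source entity
increases (+1) or decreases (−1) the target entity. Entities are typed
(protein, transcript, compound, process, phenotype, other); only
transcript-kind nodes are comparable with expression data. Duplicate
(source, sign, target) triples collapse with merged evidence; a pair of
contradictory statements (both signs present) is deliberately kept and
surfaces later as ambiguity.

A **hypothesis** is an (entity, direction) pair. Its predicted effect on
a transcript `t` is the hypothesis direction times the product of edge
signs along a statement chain from the entity to `t`. Chains are simple
paths (no node revisited — this prevents unbounded sign flipping and is
the convention in signed-path reasoning) of length at most `depth`.
When chains of both signs reach `t`, the prediction is *ambiguous*; the
number of chains supporting a sign is irrelevant, because counts of
explained genes, not of assertions, drive all downstream statistics.

Comparing predictions with the observed significant transcripts of the
mapped universe partitions them into *correct* (predicted sign equals
observed), *incorrect* (opposite), and *ambiguous*. Two statistics
quantify each hypothesis.

**Enrichment.** Ignoring direction, is the downstream set of the
hypothesis unusually rich in significant transcripts? With universe size
`N`, significant count `K`, downstream size `n` (non-ambiguous
predictions only) and hits `k = n_correct + n_incorrect`, the one-sided
Fisher exact p-value is the hypergeometric tail `P(X >= k)`.

**Correctness.** The score `S = n_correct − n_incorrect` rewards getting
directions right. Its null model re-assigns the observed `G_up` up-labels
and `G_down` down-labels uniformly onto distinct nodes of the `N`-node
universe. Writing `u+`, `u−` for up/down labels landing in the
predicted-up set (size `d_up`) and `v+`, `v−` for the predicted-down set
(size `d_down`),

```
S = (u+ + v−) − (u− + v+),
```

a function of a four-component multivariate hypergeometric vector. The
package computes the exact probability mass function by summing the
closed-form placement probabilities over the feasible `(u+, u−, v+, v−)`
grid — a polynomial-time convolution, never an enumeration of label
assignments. The correctness p-value is the exact upper tail
`P(S >= s)`. Two identities anchor the implementation: the pmf must sum
to 1 (enforced at 1e−9, computed via `lchoose` in log space to avoid
overflow), and `E[S] = (G_up − G_down)(d_up − d_down)/N` by linearity,
verified numerically in the tests.

```{r null-example}
nd <- correctness_null(N = 12, G_up = 4, G_down = 3, d_up = 3, d_down = 2)
nd
sum(nd$support * nd$pmf)        # equals (4-3)*(3-2)/12
correctness_pvalue(3, nd)
```

## Interpretation decisions

Several points are under-determined by the printed formulas of the
approach; the package fixes them as follows and exposes the alternatives
where reasonable.

- **Ambiguous predictions** are excluded from the enrichment hit count
  and draw size, from the score, and from the null's `d_up`/`d_down`.
  This is the literal reading of `#correct + #incorrect` and
  `#correct − #incorrect`; an ambiguous gene supports neither direction.
- **The null universe is the mapped measured universe** (transcripts both
  measured and present in the knowledge base), not all knowledge-base
  nodes: the labels being re-assigned are properties of the experiment,
  so margins must match the data. Mapping is opaque-string, case-sensitive
  identifier equality; identifier translation belongs upstream.
- **Enrichment is one-sided** (over-representation). The gene-set
  enrichment operation (`go_enrichment`) is two-sided by design, since
  depletion of significance in a category is informative there.
- **No multiple-testing correction across hypotheses**: admission uses
  raw p-value cutoffs (below), and hypotheses are strongly dependent
  through shared targets; `stats::p.adjust` can be applied to the results
  table by users who want FDR control.
- **Ranking** uses ascending correctness p-value with competition ranks
  (ties share the minimum rank), breaking ties by enrichment p-value then
  entity id. The correctness p-value is the primary evidence measure, so
  it is the natural ordering key.
- **Default depth is 1** (direct statements onto transcripts),
  configurable up to the `depth` argument's value. Depth 1 matches the
  per-assertion evidence display of causal-network browsers; deeper
  propagation multiplies chains whose biological support decays quickly,
  so it is opt-in rather than default. Transcript nodes may serve as
  intermediates of longer chains; nothing forbids a transcript regulating
  another entity.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `depth` | 1 | maximum statement-chain length (hops) |
| `min_targets` | 1 (3 in the pipeline) | reachable transcripts needed to enumerate an entity |
| `max_correctness_p` | 0.01 | admission cutoff, strict |
| `max_enrichment_p` | 0.01 | admission cutoff, strict |
| `min_correct` | 3 | minimum correctly explained changes, inclusive |
| `min_percent_correct` | 0.60 | minimum fraction correct, inclusive |
| `cluster_threshold` | 0.15 | minimum average evidence cosine to merge |
| `p_cutoff`, `fc_cutoff` | 0.05, 1.3 | significance calls on the expression table |

The pipeline default `min_targets = 3` simply avoids scoring entities
that could never satisfy `min_correct = 3`.

## Clustering and models

The supporting evidence of a hypothesis is the set of (gene, explained
direction) pairs it correctly explains; incorrect explanations can be
added as signed features via `include_incorrect`, but are not support and
are off by default. Similarity is the cosine of the binary feature
vectors, `|a ∩ b| / sqrt(|a||b|)` — 1 for identical evidence, 0 for
disjoint or empty. Agglomeration is average-linkage (mean pairwise
cosine between clusters) and merges while the best pair is at or above
the threshold; there is no fixed cluster count and singletons are
allowed. Determinism matters for reproducible outputs, so exact ties
(within 1e−9) merge the lexicographically smallest pair of clusters,
keyed by each cluster's smallest member label; the partition is then
invariant to input order. Hypotheses with empty evidence never merge:
with them, a threshold of 0 would glue unrelated hypotheses through
vacuous zero similarities. Cluster ids are assigned by descending size,
then best member rank, then smallest label.

Merging a subset yields the model statistics: the fraction of
significant mapped changes covered by the union of correct explanations
(monotone as members are added), per-transcript overlap counts, and
contradictions (genes correct for one member, incorrect for another).
Because the original platform prints no single "overlap" definition,
both the transcript-level counts and a scalar summary (fraction of the
union explained by ≥ 2 members) are reported. The evidence matrix
(+1/−1/0/absent) has row marginals equal to the member classifications
by construction. Exports (SIF, GraphML, node/edge TSVs) encode hypothesis
direction, per-edge predicted sign and observed sign — the usual
blue/yellow/red/green color semantics of causal-network views — plus
inter-hypothesis edges wherever a knowledge-base statement links two
member entities.

## The synthetic generator

`simulate_kb`/`simulate_experiment` generate the study conditions used
throughout the tests: 200 regulators, 2,000 transcripts, mean out-degree
15, 30% negative edges, 2% contradictory duplicates; 5 planted active
regulators with random directions, whose direct targets respond
consistently with probability 0.8 and with flipped sign with probability
0.05, over a 2% background significance rate. This emulates the regime
of a few hundred significant changes in a few-thousand-gene measured
universe with a handful of genuine upstream drivers — strong but noisy
signal, sparse decoy overlap. A `mapping_rate` option injects
measured-but-unmapped significant transcripts to emulate incomplete
knowledge-base coverage (roughly three quarters of changed genes mapping
is typical of commercial content). Optional regulator-to-regulator edges
exercise depth > 1.

What the generator does **not** emulate: correlated co-regulation among
decoys, hub regulators with thousands of targets, scale-free degree
structure, probe-level noise or the upstream normalization/moderated-test
pipeline (the package consumes already-called tables), and curation
biases of real literature networks. Passing recovery tests therefore
demonstrates correctness of the machinery and sane statistical behavior
at desk scale, not performance on licensed content.

All randomness is seeded; the knowledge base and the experiment use
distinct streams derived from the one seed (`seed`, `seed + 1`), so
outputs are bit-reproducible per configuration.

## Numerical choices and degenerate inputs

- Null pmfs are computed with `lchoose` and exponentiated per grid cell;
  the feasibility constraints prune the grid before any evaluation. A
  hypothesis with no predictions has the degenerate null `P(S = 0) = 1`.
- A score above the null support yields the exact empty tail, 0; at or
  below the minimum, exactly 1. Observed scores always lie in the
  support, so reported correctness p-values are in (0, 1].
- An empty downstream set gives enrichment p = 1 with a warning rather
  than an error: the hypothesis is uninformative, not invalid.
- `percent_correct` is undefined (NA) when a hypothesis explains only
  ambiguous genes; the admission filter drops such rows.
- Gene-set odds ratios use the sample cross-product, reported as `Inf`
  when a term is exhausted by the significant set and as 1 for the
  degenerate all-or-nothing margins.
- Desirability anchors (effect saturating at odds ratio 10, −log10 p
  saturating at 5, size peak at 20 genes within [2, 500]) are
  conventions — the composite is the geometric mean of three Derringer
  ramps, and every anchor is an argument.

## Verification strategy and problem sizes

The test suite checks every exact computation against an independent
brute-force oracle: the null pmf against exhaustive enumeration of all
label placements on universes up to N = 12 and against a 100,000-draw
permutation estimate at N = 500; enrichment p-values against direct
hypergeometric summation on random tables up to N = 30; chain
propagation against exhaustive simple-path listing on random graphs;
clustering against a naive re-computing agglomerator on batches of up to
12 hypotheses; filtering against row-by-row predicate re-evaluation.
Type-I control of the correctness p-value is measured on 1,000 simulated
null experiments (25 regulators, 250 transcripts, 5% background), and
planted-regulator recovery on 20 seeded simulations at the default
generator settings. These sizes were chosen as the smallest that make
the checks sharp; all are exercised by `tests/testthat` and re-computed
by `scripts/acceptance.R`.

## Known limitations

- Depth > 3 is untested territory and slow on dense graphs (simple-path
  enumeration is exponential in the worst case).
- The correctness null conditions on the observed label counts and the
  predicted sets; it does not model uncertainty in the knowledge base
  itself (wrong or missing statements).
- Evidence clustering is binary; weighting features by assertion counts
  or evidence quality is deliberately out of scope.
- Identifier mapping is exact string equality; cross-namespace
  translation must happen before `read_expression`/`parse_kb`.
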