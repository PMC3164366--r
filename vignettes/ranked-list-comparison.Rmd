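---
title: "Comparing ranked gene lists without thresholds: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing ranked gene lists without thresholds: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(listcomp)
```

## The problem

Two differential-expression experiments rarely agree on which genes "made
the cut": platforms differ in dynamic range, protocols differ in replicate
variance, and any fixed p-value or fold-change threshold lands in a
different place in each study. Intersecting two thresholded gene sets
therefore conflates real biological disagreement with arbitrary cutoff
placement. `listcomp` takes the threshold out of the question. Both
experiments are reduced to *ranked* gene lists — genes ordered by the
magnitude of their expression change, separately for up- and
down-regulation — and the question becomes: do the tops of the two rankings
share more genes than chance allows, and down to what depth?

## The marching algorithm

Let `N` be the number of genes both experiments measure (after filtering),
and select the top `m` genes of each list. If the two experiments were
unrelated, the overlap `k` between the two selections would behave like the
intersection of two random `m`-subsets of `N` genes, so under the null

$$P(X = k) = \frac{\binom{m}{k}\binom{N-m}{m-k}}{\binom{N}{m}}, \qquad
  P(X \ge k^{*}) = \sum_{k=k^{*}}^{m} P(X=k),$$

the hypergeometric distribution and its upper tail. `compare_lists()` starts
at `m = step` (default 100 genes) and repeatedly adds `step` genes to both
selections, retaining a step while two criteria hold at level `alpha`
(default 0.05):

1. **overlap significance** — `overlap_pvalue(N, m, k) < alpha`;
2. **increment significance** — the *growth* of the overlap since the
   previous step exceeds what random extension of both lists would produce
   (`increment_pvalue < alpha`; the first step has no predecessor, so only
   criterion 1 applies there).

The procedure stops at the first failure and reports the last depth `m*`
where both criteria held, the `k*` genes common to both top-`m*` selections,
and the full step trace. Criterion 2 is what makes the estimate of the
common set *size* honest: deep in the ranks the cumulative overlap of two
related lists can remain nominally significant long after the newly added
genes have degenerated to chance-level agreement, and the increment test
stops the march exactly there.

### The increment null

Conditional on the previous configuration — `m_prev` genes selected per
list with `k_prev` shared — the next `Δm` ranks of each list are modelled as
exchangeable draws from that list's remaining genes. The overlap gain
decomposes as `Δk = X + Y + Z`: new A-genes already selected by B
(hypergeometric over A's remaining pool), the mirror count for B
(independent, because the two lists' orders are independent under the
null), and genes newly picked by both (hypergeometric over the
never-selected pool, conditional on X and Y). `increment_pvalue()`
convolves this decomposition exactly, dropping terms below 1e-16 relative
mass, and sums the tail smallest-terms-first. The package validates this
derivation against a direct permutation oracle (randomly extending both
lists 10^5 times) rather than trusting the algebra: see
`test-acceptance.R`.

### Numerical choices

All binomial coefficients are computed in log space via log-gamma, so
universes of tens of thousands of genes cannot overflow. Tail sums
accumulate from the smallest terms to limit floating-point cancellation;
on every universe up to 60 genes the pmf sums to 1 within 1e-12, and up to
14 genes the tail matches exhaustive enumeration over all subset pairs to
1e-12. Ranking ties are broken alphabetically by gene symbol, which makes
every result deterministic. Degenerate inputs fail loudly: mismatched
universes or directions, empty lists, and non-positive steps are contract
errors rather than silent coercions.

One boundary case is worth knowing: if a ranked list spans its entire
universe (every measured gene changed in one direction), the final step
selects all `N` genes in both lists, the overlap is forced, and its tail
probability is 1 — so the march always stops one step short of `N`. In real
data directional lists are strict subsets of the universe and the case does
not arise.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `step` | 100 | genes | rank increment per iteration; smaller steps localise the stopping point at more multiple testing |
| `alpha` | 0.05 | probability | level applied to both criteria; no across-step correction by default (`bonferroni = TRUE` available) |
| `percentile` | 0.25 | fraction | low-expression filter: probesets below this quantile of per-probeset mean scores in *both* conditions are dropped |
| `fold_change_mode` | `"log_diff"` | — | difference of mean log2 scores (a log2 fold-change); `"raw_ratio"` is the literal ratio of the two means, exposed for comparison but scale-dependent |
| `window` | — | ranks | maximum rank displacement of the windowed shuffle |

The `alpha` default is the conventional 0.05; the sequential structure of
the two criteria already guards against runaway selection, which is why no
multiple-testing correction is applied across steps by default. The
quantile convention is linear interpolation (`stats::quantile` type 7),
fixed and regression-tested. The per-condition (rather than pooled)
quantile is used for filtering: each condition's distribution of
per-probeset means sets its own bar.

## Preprocessing conventions

`compute_fold_changes()` takes the difference of mean log2 expression
scores between treatment and control — the log2 of the ratio of
geometric means on the linear scale, the standard definition for
log-transformed microarray scores. A literal ratio of log2 scores would
depend on the units of the log scale, which is why it is only available as
an explicit opt-in. Genes measured by several probesets receive the
arithmetic mean of their probesets' fold-changes. Genes with fold-change
exactly zero join neither directional list but count toward `N`: they were
measured, so they are part of the population the null draws from.

When the two experiments come from different platforms,
`compare_directional()` first intersects the two gene universes and takes
`N` to be the shared-universe size. This is the convention that keeps the
hypergeometric model coherent — both top-`m` selections must be drawn from
the same population — and genes measured on only one platform are dropped
rather than being treated as automatic non-overlap.

## What the simulations emulate — and what they do not

The shuffle generators reproduce the package's two validation regimes:
`shuffle_unconstrained()` produces the null (two rankings of the same genes
with no association), and `shuffle_windowed()` produces related pairs in
which no gene moves more than `window` ranks. The windowed sampler jitters
each rank by Uniform(−window, +window) and re-sorts; because crowding in
the re-sort can push a displacement slightly past the bound, keys of
violating genes are resampled until the hard bound holds everywhere. The
draw is therefore near-uniform over the constrained permutations rather
than exactly uniform (whole-draw rejection, the obvious exact variant, has
vanishing acceptance already at a few thousand genes). At
`window ≥ n − 1` the constraint is vacuous and an exactly uniform
permutation is drawn.

`make_related_tables()` plants a fraction of genes with a shared signed
effect and adds independent Gaussian noise per table;
`make_expression_matrix()` expands a fold-change table into replicate
log2 scores with per-gene baselines drawn from a typical
normalized-intensity range (4–12 log2 units). These fixtures capture rank
structure, direction, replicate noise and probeset multiplicity. They do
*not* model probe affinity biases, batch effects, correlated gene modules,
or heavy-tailed noise — so a passing simulation suite shows the algorithm
does what its model claims, not that the model captures every pathology of
real microarray data.

Default validation sizes — universes of 2000–5000 genes, step 100, windows
of 100 ranks, a planted fraction of 0.3 at effect size 2 against noise 0.5
— were chosen once as representative of a genome-scale experiment and are
the sizes the test suite and the acceptance script run at.

## Clustering many experiments

For `C` conditions, all pairwise signature sizes `k_ij` convert to the
distance `m_ij = max(k_lm) − k_ij` (maximum over off-diagonal pairs), so
the most-overlapping pair sits at distance zero. Pairs with no significant
overlap contribute `k_ij = 0`, and `k_ij` is the sum of up- and
down-overlaps by default (`direction` restricts it). Complete-linkage
agglomeration is delegated to `stats::hclust`; conditions are sorted
alphabetically first so the tree is invariant under input permutation, and
the hand-rolled reference implementation in the test suite confirms merge
orders and heights to 1e-9. Including self-pairs in the maximum would only
shift every distance by a constant without changing the topology;
off-diagonal is the natural reading of "compare experiments". Trees
serialize to Newick with the usual ultrametric convention (leaf depth =
half the root merge height).

## Cross-species signatures

`conserved_signature()` works at the homolog-*pair* level: a pair is
concordant-up when its A-endpoint is up-regulated in species A and its
B-endpoint up-regulated in species B, likewise down; pairs present in both
signatures with opposite directions are reported as *discordant* rather
than dropped, because a direction conflict is biological information. With
many-to-many homology a gene is included as soon as any homolog agrees
("any-homolog" rule) — the pair table preserves the detail needed for a
stricter unique-homolog analysis. The reporting species for the collapsed
sets is configurable; counts are symmetric in the two species by
construction.

## Known limitations

* The increment-test null treats ranks below the current depth as
  exchangeable; a list with strong within-step structure (massive ties from
  quantized scores) weakens that assumption. Ties are deterministic but the
  null does not model them specially.
* The marching procedure stops at the first criterion failure; it does not
  scan all depths for the deepest significant one. A single noisy step can
  therefore truncate the march early — visible in the step trace, which is
  always returned in full (`trace_full = TRUE` extends it past the stop for
  plotting).
* Distances from overlap counts are not metric in the triangle-inequality
  sense; complete linkage does not require metricity, but other linkage
  criteria offered behind the `method` argument are untested here.
* The windowed shuffle is near-uniform, not exactly uniform, over its
  constrained permutation set (see above).

## A worked example

```{r example}
sim <- make_related_tables(N = 2000, frac_shared = 0.3, effect_size = 2,
                           noise_sd = 0.5, seed = 42)
dc <- compare_directional(sim$table_a, sim$table_b, step = 100)
glance(dc)
venn_counts(dc)
f1 <- {
  tp <- length(intersect(dc$signature$gene, sim$planted$gene))
  2 * tp / (nrow(dc$signature) + nrow(sim$planted))
}
f1
```

```{r plot, fig.width = 6, fig.height = 3.5}
autoplot(dc)
```
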