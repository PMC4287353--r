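---
title: "Alignment-free clustering of multi-domain proteins with local matching scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free clustering of multi-domain proteins with local matching scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmsclust)
```

## The problem

Multi-domain proteins are the norm, not the exception, and they are exactly
where alignment-based comparison breaks down: two proteins built from the
same domains in a different order, or related by a circular permutation,
share most of their sequence content yet align poorly. Clustering driven by
alignment scores then separates proteins that belong together. `lmsclust`
clusters full-length amino-acid sequences without aligning them, so domain
order, sequence length and tethered inter-domain regions stop being
confounders while still contributing signal.

## The model

### Local Matching Score

For two sequences $s$ and $s'$, every consecutive five-residue fragment of
$s$ is looked up in $s'$ by exact string match. A residue is *covered* when
it lies inside at least one shared fragment. The Local Matching Score is

$$\mathrm{LMS}(s, s') = \sum_{i \in C(s)} M[i,i] \;+\; \sum_{j \in C(s')} M[j,j],$$

where $C(\cdot)$ are the covered position sets and $M$ is BLOSUM62 (only its
diagonal enters). The score is turned into a distance by

$$d(s, s') = 1 - \frac{\mathrm{LMS}(s, s')}{S(s) + S(s')},$$

with $S(x)$ the full diagonal sum of $x$ (and $S(x) = 0$ for sequences too
short to contain a fragment). Because each side's covered sum is bounded by
its full diagonal sum, $d \in [0, 1]$, $d = 0$ for identical sequences over
the standard alphabet, and $d = 1$ when no fragment is shared.

Two points here were genuinely open design choices and are worth stating as
such. First, "matching" is exact string equality of 5-mers: no
substitutable-residue expansion is applied, which keeps the computation
deterministic and directly checkable against a brute-force double loop.
Second, the normalization denominator $S(s) + S(s')$ is the tightest
self-referential bound that guarantees the $[0,1]$ range and $d(s,s) = 0$;
other denominators (e.g. $2\min(S(s), S(s'))$) would not give both. The
distance is *not* guaranteed to satisfy the triangle inequality, and no
code here assumes it does.

Unknown residues are handled conservatively: the nonstandard one-letter
codes B, Z, U, O and J are mapped to `X` on input, any fragment containing
`X` is excluded from matching (an `X` never matches anything, not even
another `X`), but `X` positions still count in the denominator with their
own diagonal score. Unknown sequence content can therefore dilute
similarity but never manufacture it.

### Clustering and tree parsing

The pairwise distances feed Ward's minimum-variance agglomeration in its
classic form: the Lance–Williams update applied to the distances as given
(`stats::hclust(method = "ward.D")`). Ward merge heights routinely exceed 1
even when all input distances lie in `[0, 1]`, so [cut_tree()] first
rescales all heights by the maximum (the root then sits at 1) and cuts at a
user cut-off $x \in [0, 1]$: clusters are the connected components after
removing every merge above $x$. The cluster count is a non-increasing step
function of $x$; $x = 1$ gives one cluster and $x = 0$ gives singletons
whenever all merge heights are positive. Clusters are numbered 1..K by
first appearance in input order, so output files are stable across runs.
The default cut-off surfaced by the command-line pipeline examples, 0.55,
is the threshold used for this method's reference runs on curated data
sets.

### Domain-architecture similarity

When a tab-delimited architecture file is supplied (one protein per line,
domains N- to C-terminal), each cluster is scored over all unordered member
pairs with three indices, each in $[0, 1]$ and each capturing one aspect:

* **Jaccard** — shared domain *types* over distinct types. Types, not
  occurrences: copy number is deliberately left to the third index so the
  three stay orthogonal.
* **Goodman–Kruskal $\gamma$ (rescaled)** — order conservation. Over all
  pairs of distinct shared types, $S$ counts pairs in the same N→C order
  (by first occurrence) and $R$ pairs reversed;
  $\gamma = (S-R)/(S+R)$ is reported as $(\gamma+1)/2$. With fewer than two
  shared types order conservation is vacuously true and the score is 1.
* **Duplication similarity** — mean over shared types of
  $\min(c_P, c_Q)/\max(c_P, c_Q)$, where $c$ is the copy number. The
  formula is this package's own choice of a copy-number similarity bounded
  by $[0,1]$; published variants differ, so treat absolute values as
  package-specific.

Per-cluster means and *population* standard deviations (divide by the
number of pairs, matching "all combinations of pairs") are reported;
singleton or unannotated clusters yield `NA` rather than errors.

### Robinson–Foulds comparison

`rf_distance()` compares two trees on the same leaves as unrooted
topologies: the distance is the size of the symmetric difference of their
non-trivial bipartition sets, with a normalized variant dividing by
$2(n-3)$. The implementation is a plain set comparison — at the scale this
package targets (up to a few thousand leaves), hashing schemes are an
optimization, not a semantic difference.

## The synthetic generator

`generate_dataset()` builds families from reusable domain blocks: each
domain type gets one random master sequence, each family an ordered
architecture of types, and each member is the concatenation of its masters
with i.i.d. point substitutions (replacements uniform over the other 19
residues — the simplest null that still stresses exact 5-mer matching). A
fraction of members get a random domain-order shuffle and a fraction a
circular rotation, with the architecture metadata updated to match. The
defaults are the study conditions used throughout the tests: 3 families × 8
members, domain masters of 30–60 residues, substitution rate 0.05, a
quarter of each family shuffled, and one promiscuous domain type shared by
all families (the regime where domain promiscuity confuses domain-level
classification).

What the generator does *not* emulate: indels, rate heterogeneity across
sites, compositional bias, and realistic domain-length distributions.
Passing tests on this generator therefore demonstrate the method's
robustness to substitutions and rearrangements, not performance on real
proteomes.

```{r example}
set.seed(1)
ds <- generate_dataset(synth_config(seed = 11))
d <- distance_matrix(ds$records)
hc <- ward_linkage(d)
ct <- cut_tree(hc, 0.55)
table(cluster = ct$labels, family = ds$truth[names(ct$labels)])
```

## Numerical choices

* Scores are exact integers up to the final division, so distances are
  bit-reproducible across platforms.
* `hclust`'s own deterministic tie handling is kept as-is; identical
  inputs give identical trees, which the tests assert.
* Cutting uses `cutree(h = x * max(height))`; a merge exactly at the
  cut-off height stays merged. A degenerate tree (all heights 0, e.g. all
  sequences identical) cuts to a single cluster at any $x$, with a warning
  from the pipeline rather than an error.
* The pipeline's problem sizes in tests and in the acceptance script (24
  sequences per dataset, 8-point matrices for the clustering cross-checks,
  12-leaf trees for RF) were chosen as the smallest sizes at which every
  failure mode the suite probes — repeated k-mers, ties, promiscuous
  domains, rearrangements — actually occurs.

## Known limitations

* The LMS distance is not a metric; do not feed it to methods that require
  the triangle inequality.
* Exact 5-mer matching loses sensitivity for very divergent homologs
  (substitution rates well above ~0.1 leave few shared 5-mers).
* Sequences shorter than 5 residues carry no signal; their distance to
  everything is defined as 1 with a warning.
* The duplication-similarity index is a package-defined formula (see
  above); compare its values only within runs of this package.
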