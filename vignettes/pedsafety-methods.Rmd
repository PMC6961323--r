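---
title: "Methods: mining, clustering and safety-scoring drug–diagnosis associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining, clustering and safety-scoring drug–diagnosis associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedsafety)
```

## The statistical model

### The pair universe

The unit of observation is the *drug–diagnosis association pair*: one
drug code and one diagnosis code recorded under the same inpatient
encounter. An encounter with `|D|` distinct drugs and `|G|` distinct
diagnoses contributes the full cross product `|D| × |G|` of pairs, so the
cohort defines a universe of `N = Σ_e |D_e| × |G_e|` pairs. For a pair
(d, g):

* `K` — pairs involving drug d (`Σ_e 1[d ∈ D_e] · |G_e|`),
* `n` — pairs involving diagnosis g (`Σ_e 1[g ∈ G_e] · |D_e|`),
* `k` — encounters in which d and g co-occur.

These margins satisfy `ΣK = Σn = Σk = N` by construction, which is the
consistency check `build_pairs()` enforces and the tests assert.
Repeated administrations of the same drug within one encounter are
collapsed to a single event before counting: distinct-pair counting is
what makes this universe well defined, and it keeps `k` bounded by the
number of encounters. A consequence worth noting is that the universe is
a multiset over encounters, not an independence model across pairs; the
hypergeometric test below is a screening statistic, not a causal model.

### Enrichment and multiplicity

Association strength is the one-sided upper-tail hypergeometric
probability `P(X ≥ k)` with population `N`, success count `K` and draw
count `n` — over-representation only, since a drug being given *less*
often than chance with a diagnosis is not evidence of an indication. The
implementation calls the survival function at `k − 1`
(`phyper(k - 1, K, N - K, n, lower.tail = FALSE)`), which avoids the
catastrophic cancellation of `1 − CDF` at large `k`. The test suite
checks it against brute-force summation of `C(K,i)·C(N−K,n−i)/C(N,n)`
for every admissible configuration with `N ≤ 20` at `1e-12`.

Bonferroni correction controls the family-wise error rate:
`p_adj = min(1, m · p_raw)`. The tested family defaults to the pairs
actually observed to co-occur (`k ≥ 1`) — zero-count pairs have
`p_raw = 1` and are not meaningful hypotheses — and `m` can be widened to
the full `|drugs| × |diagnoses|` grid with `enrich(..., family = "all")`
for users who prefer the conservative reading. The default `alpha` is
0.05 on the adjusted scale. On null cohorts (the generator with
`signal_prob = 0`) the realized family-wise false-positive rate measured
over 200 replicates is far below alpha, as expected from Bonferroni's
conservativeness on positively dependent counts.

### Distances between drugs

Significant associations are binarized (adjusted `P < alpha` → 1) and
each drug is identified with its set of significant diagnoses. The drug–
drug distance is the Jaccard distance between these sets. Two
conventions matter:

* **empty vs empty = 0.** The Jaccard ratio is undefined for two empty
  sets; defining the distance as 0 makes all never-associated drugs
  mutually indistinguishable, so they form a single coherent cluster —
  the structural analogue of the "no associated diagnosis" cluster that
  appears in real cohorts.
* **empty vs nonempty = 1.** Such drugs share nothing, and the maximum
  distance keeps the no-association pool well separated.

The resulting matrix is a true metric (symmetry, zero diagonal, triangle
inequality), which the suite verifies on randomized binary matrices.

## Clustering

### Representation and algorithm

k-means needs coordinates, not distances, so each drug is represented by
its row of the distance matrix — its profile of distances to every drug.
This is the standard device for feeding a distance matrix to a centroid
method: drugs with similar diagnosis sets have similar profiles, and the
no-association drugs share an identical profile. Restarts use k-means++
seeding over the *distinct* rows (`n_init` restarts, best
within-cluster sum of squares kept); sampling centers from distinct rows
means duplicated profiles can never produce an empty cluster. When there
are fewer distinct profiles than requested clusters — the fully
degenerate case of a cohort with no significant association at all — the
partition falls back to a deterministic split of the duplicate groups
with a warning, so downstream stages keep running.

### Choosing k by bootstrap stability

For each candidate k the drugs are clustered once on the full data
(reference), then `B` bootstrap resamples of the drugs (with
replacement) are re-clustered; each reference cluster is scored by its
best Jaccard membership overlap with any bootstrap cluster, restricted
to the drugs present in the resample, and the statistic is the mean over
clusters and resamples. The chosen k maximizes this mean, ties broken
toward the smallest k (parsimony). A reference cluster with no member in
a given resample contributes nothing to that resample's mean — exclusion
keeps the statistic in [0, 1] rather than penalizing small clusters for
sampling noise.

Defaults are `k_min = 10`, `k_max = 50` (the scan range appropriate for
a hospital-scale formulary of several hundred drugs), `B = 100`
resamples and `n_init = 10` restarts. The validation suite uses smaller
settings chosen once for its synthetic problem sizes — 100 drugs in 5
planted blocks scanned over k = 2..10 with `B = 20` — where the
stability profile is sharply peaked and additional resamples do not move
the argmax. All stochastic stages derive their seeds from a single
pipeline seed via a stable hash of the stage name, so any stage can be
rerun in isolation and full runs are bit-reproducible.

### Kernel sets, hierarchy, embedding

Each cluster's *kernel diagnosis set* is the set of diagnoses
significantly associated with at least a fraction `kernel_min_share` of
its member drugs. The default share is 0, i.e. the union over members:
kernels are descriptive summaries, and the union keeps rare but real
within-cluster indications visible; users who want tighter kernels raise
the share (1 gives the intersection). Clusters are themselves organized
into a dendrogram by average-linkage agglomeration on the Jaccard
distances between kernel sets — the same set distance used for drugs,
for consistency — and the 2-D map uses classical multidimensional
scaling (principal coordinates of the double-centered squared-distance
matrix), deterministic up to sign.

## The pediatric safety scale

The 0–5 safety level encodes the youngest population covered by a drug's
pediatric labeling:

| Level | Youngest labeled population |
|---|---|
| 5 | preterm newborn infants |
| 4 | full-term newborns (0–28 days) |
| 3 | infants and toddlers (>28 days to 23 months) |
| 2 | children (2–11 years), or a pediatric indication without an age |
| 1 | adolescents only (12–18 years) |
| 0 | no pediatric labeling, not established, or contraindicated |

Decisions embedded in the mapping:

* A numeric minimum labeled age takes precedence over the statement
  class and is binned on the boundaries above; the 23-month/2-year edge
  is resolved as ≥24 months → child. A negative age denotes a
  gestational (preterm) indication; a minimum age above 18 years is
  treated as no pediatric labeling, with a warning.
* A contraindication dominates any age range: such drugs are level 0
  regardless of what else the label says.
* When a drug carries different labeled ages for different indications,
  the minimum age across indications is used — an assumption, flagged
  here, since labels rarely say which indication drove pediatric use.
* Drugs conventionally assumed safe without formal labeling (traditional
  preparations, externally applied products) are still level 0, but the
  `provenance` attribute preserves the originating statement class so
  the two level-0 subgroups remain distinguishable in summaries.

Cluster-level safety is the arithmetic mean of member levels with the
sample (n−1) standard deviation, 0 by convention for singletons, plus the
per-level count and proportion distribution. The size-weighted mean of
cluster means always reproduces the grand mean — an invariant the tests
assert.

## Cohort comparison

Two cohorts are aligned on the union of their diagnosis (or drug)
vocabularies. Per diagnosis: presence flags, per-mille incidence
(1000 × encounters carrying it / total encounters), the number of
significantly associated drugs in each cohort, and the size of the
intersection of the two drug sets. Per drug: presence, deduplicated use
volume (encounters in which it was given — administration counts are not
comparable across hospitals, encounter counts are), associated-diagnosis
counts and overlap. Rows are grouped by average-linkage hierarchical
clustering on standardized features — presence flags as 0/1, count-like
columns log1p-transformed then z-scored (log1p because incidences and
association counts are heavy-tailed; constant columns are left
unscaled) — and the tree is cut at a configurable group count (7 for
diagnoses and 4 for drugs are sensible defaults for hospital-scale
data). Group composition is then summarized as percentages per coding
category (ICD-10 chapter, first-level ATC class), with unmapped codes
tallied explicitly.

## The synthetic cohort generator

The generator emulates the structure the method is designed to detect: a
block model in which drugs and diagnoses partition into
condition-specific pools. Each encounter belongs to one block; diagnosis
slots draw from the block's diagnosis pool except for a uniform
background draw with probability `noise_prob` (default 0.05), and drug
slots draw from the block's drug pool with probability `signal_prob`,
otherwise uniformly from all drugs. Event counts per encounter are
Poisson (means 3 and 3) — the simplest model producing variable encounter
sizes. A mandatory pool of unassociated drugs (background-only) exercises
the empty-set Jaccard convention and the no-association cluster pathway
in every preset. `signal_prob = 0` severs drugs from diagnoses entirely,
giving an exact null for family-wise error calibration.

Presets: `strong` (5 blocks, 100 drugs of which 10 unassociated, 150
diagnoses, 5000 encounters, `signal_prob = 0.95`) is the recoverability
regression standard — the full pipeline must recover the planted
partition with adjusted Rand index ≥ 0.9 and the stability scan must
find 5 or 6 clusters (the unassociated pool may or may not claim its own
cluster); `null` (50 drugs, 80 diagnoses, 2000 encounters) is the
calibration standard; `weak` halves the signal for power exploration.
Label generation draws one canonical statement class per safety level
with configurable level probabilities; the default probabilities imitate
a realistic formulary in which nearly half the drugs sit at level 0.

What the generator does *not* emulate: real marginal frequency
distributions of ICD-10/ATC codes (real diagnosis frequencies are far
more skewed), age structure, comorbidity correlation between blocks, or
drugs legitimately shared across conditions. Passing the planted-recovery
tests therefore demonstrates correctness of the machinery, not expected
cluster quality on real EMRs, where block overlap and coding noise will
lower stability scores and blur cluster boundaries.

## Numerical and degenerate-input choices

* Hypergeometric p-values via the survival function, never `1 − CDF`.
* `p_adj` capped at 1; significance strictly `p_adj < alpha`.
* Codes are whitespace-trimmed, case-preserved strings; diagnosis codes
  are not truncated to ICD-10 categories — truncation, where wanted, is a
  preprocessing step upstream of the package.
* An input with no encounter containing both a drug and a diagnosis is an
  explicit error (empty universe), not an empty result.
* A cohort with zero significant associations runs through the full
  pipeline: all distances are 0, the partition degrades to the
  deterministic split described above, kernels are empty, and artifacts
  are still written.
* Ties in `select_k` resolve to the smallest k; k-means ties are resolved
  by the restart with the lowest within-cluster sum of squares under a
  fixed derived seed.

## Known limitations

Low-incidence diseases and rarely used drugs cannot reach Bonferroni
significance at any realistic cohort size, so absence of a significant
association never means absence of treatment. The Bonferroni family
default (`k ≥ 1` pairs) is the more powerful choice but still
conservative under the positive dependence typical of co-occurrence
counts; a false-discovery-rate alternative is deliberately out of scope
for this version. Cluster labels are arbitrary integers — the clinical
interpretation of a cluster (which condition it represents) requires
reading its kernel diagnoses and is not automated.
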