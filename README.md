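# pedsafety

Quantitative pediatric drug-safety profiling from electronic medical
records (EMRs).

Most drugs prescribed to hospitalized children have never been formally
evaluated in pediatric populations: their labels either carry no pediatric
information at all or state that safety and efficacy in children have not
been established. `pedsafety` implements a computational method for
measuring this problem from routine inpatient EMR data. It is aimed at
pharmacoepidemiologists and clinical-informatics teams who have
encounter-level medication and diagnosis records and want a reproducible,
quantitative picture of which clinical conditions are treated with
well-labeled drugs and which are not.

## The method

1. **Association mining.** Every drug code and diagnosis code recorded
   under the same inpatient encounter forms a drug–diagnosis association
   pair. Over the whole cohort this defines a universe of
   `N = Σ_e |D_e| × |G_e|` pairs. A pair (d, g) observed to co-occur in
   `k` encounters, with `K` pairs involving drug d and `n` pairs involving
   diagnosis g, is scored with the one-sided hypergeometric tail
   `P(X ≥ k)` (over-representation under random pairing), computed with
   `phyper`. Bonferroni correction over the tested family controls the
   family-wise error rate; associations with adjusted `P < 0.05` are
   significant.
2. **Drug distances.** Significant associations are binarized into a
   drugs × diagnoses 0/1 matrix. Row `d_i` is the significant-diagnosis
   set of drug i, and drugs are compared by Jaccard distance
   `d_J(d_i, d_j) = 1 − |d_i ∩ d_j| / |d_i ∪ d_j|` (two empty sets have
   distance 0, so never-associated drugs collect into one cluster).
3. **Clustering.** Drugs are partitioned by k-means on their
   distance-matrix rows; the cluster count k is chosen by bootstrap
   cluster stability (mean cluster-wise Jaccard index over resamples of
   the drugs), scanning a candidate range (default 10–50). Each cluster
   gets a kernel diagnosis set, an inter-cluster hierarchy, and 2-D
   classical-MDS coordinates.
4. **Safety scoring.** Each drug's pediatric labeling statement maps to a
   0–5 safety level keyed to the youngest labeled population (5 preterm,
   4 newborn 0–28 days, 3 infant/toddler to 23 months, 2 child 2–11 years
   or unaged pediatric indication, 1 adolescent 12–18 years, 0 no
   pediatric labeling / not established / contraindicated). Levels are
   averaged per drug cluster, yielding safety scores per clinical
   condition.
5. **Cohort comparison.** Two cohorts (e.g. a children's hospital and a
   general hospital) are aligned by diagnosis and by drug: per-mille
   incidences, use volumes, significant-association counts and their
   overlap, plus hierarchical groupings of the aligned rows and ICD-10 /
   ATC category composition of each group.

A synthetic EMR generator with planted block structure
(`generate_cohort()`, presets `strong` / `null` / `weak`) makes every
stage testable without access to protected patient data.

## Worked example

```r
library(pedsafety)

cfg <- synthetic_config(n_encounters = 2000, n_drugs = 40, n_diagnoses = 60,
                        n_blocks = 4, signal_prob = 0.95,
                        n_unassociated_drugs = 5, seed = 42)
co     <- generate_cohort(cfg)
labels <- generate_labels(cfg, co$truth)

pairs <- build_pairs(co$encounters)
pairs
#> pair_counts: 14048 drug-diagnosis association pairs over 40 drugs x 60
#> diagnoses; 1438 distinct co-occurring pairs

assoc <- enrich(pairs, alpha = 0.05)
sum(assoc$significant)            # 488 significant of 1438 tested pairs
head(assoc, 3)
#>   drug_code diagnosis_code  k   K   n     N        p_raw        p_adj significant
#> 1       D15            G24 33 363 227 14048 5.777307e-16 8.307767e-13        TRUE
#> 2       D34            G52 38 420 277 14048 2.984128e-15 4.291176e-12        TRUE
#> 3       D29            G48 35 410 241 14048 3.233749e-15 4.650131e-12        TRUE

dm  <- distance_matrix(significance_matrix(assoc))
sel <- select_k(dm, clustering_config(k_min = 2, k_max = 8, B = 20,
                                      seed = 42, n_init = 5))
sel$k_best                        # 5: the 4 planted blocks + the
                                  # never-associated drug pool
cl  <- cluster_drugs(dm, sel$k_best, seed = 42)
evaluate_recovery(cl, co$truth)$ari   # 1: planted structure fully recovered

cluster_safety(cl, safety_levels(labels))[, 1:4]
#>   cluster_id n_drugs mean_level  sd_level
#> 1          1       9   1.666667 1.7320508
#> 2          2       9   1.222222 0.9718253
#> 3          3       9   2.000000 1.5000000
#> 4          4       8   2.000000 1.9272482
#> 5          5       5   0.800000 1.0954451
```

The association table reads: drug D15 and diagnosis G24 co-occurred in 33
encounters, far above what their margins (363 and 227 of 14,048 pairs)
would produce at random — the Bonferroni-adjusted p-value is 8.3e-13.
The bootstrap-stability profile peaks at 1.0 for k = 5, the clustering
matches the planted condition blocks exactly (adjusted Rand index 1), and
each cluster's mean safety level summarizes how well-labeled the drugs
for that condition are (here between 0.8 and 2.0 on the 0–5 scale).

`run_pipeline()` chains all stages and writes every artifact (association
table, 0/1 matrix, distances, partition, stability profile, kernel sets,
Newick hierarchy, MDS coordinates, safety tables, manifest) as delimited
text; `inst/scripts/pedsafety-pipeline.R` is a command-line wrapper over
it.

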