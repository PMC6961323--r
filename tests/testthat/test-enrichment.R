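test_that("pair universe enumerates the per-encounter cross product", {
  # one encounter, drugs {A,B} x diagnoses {x,y}: 4 pairs, hand-enumerated
  enc <- make_encounters(list(e1 = c("A", "B")), list(e1 = c("x", "y")))
  pc <- build_pairs(enc)
  expect_equal(pc$N, 4)
  expect_equal(unname(pc$K[c("A", "B")]), c(2, 2))
  expect_equal(unname(pc$n[c("x", "y")]), c(2, 2))
  expect_true(all(pc$pairs$k == 1))

  # encounters lacking one side contribute nothing
  pc2 <- build_pairs(make_encounters(list(e1 = "A", e2 = "B"),
                                     list(e2 = "x")))
  expect_equal(pc2$N, 1)

  # additivity over identical encounters
  pc3 <- build_pairs(make_encounters(list(e1 = "A", e2 = "A"),
                                     list(e1 = "x", e2 = "x")))
  expect_equal(pc3$N, 2)
  expect_equal(pc3$pairs$k[pc3$pairs$drug_code == "A"], 2)
})

test_that("margins always sum to the pair total", {
  co <- generate_cohort(synthetic_config(n_encounters = 300, seed = 11))
  pc <- build_pairs(co$encounters)
  expect_equal(sum(pc$K), pc$N)
  expect_equal(sum(pc$n), pc$N)
  expect_equal(sum(pc$pairs$k), pc$N)
  expect_true(all(pc$pairs$k <= pmin(pc$K[pc$pairs$drug_code],
                                     pc$n[pc$pairs$diagnosis_code])))
})

test_that("no encounter with both a drug and a diagnosis is an error", {
  enc <- make_encounters(list(e1 = "A"), list(e2 = "x"))
  expect_error(build_pairs(enc), "empty universe")
})

test_that("hypergeometric tail matches brute-force pmf summation", {
  # frozen spec example: k=4, K=4, n=5, N=10 -> 6/252
  expect_equal(hypergeom_pvalue(4, 4, 5, 10), 6 / 252, tolerance = 1e-12)
  expect_equal(hyper_tail_bruteforce(4, 4, 5, 10), 6 / 252,
               tolerance = 1e-12)
  # k = 0 is certain; degenerate universe is certain
  expect_equal(hypergeom_pvalue(0, 3, 4, 10), 1)
  expect_equal(hypergeom_pvalue(5, 5, 5, 5), 1)
  # random spot checks against the oracle
  set.seed(42)
  for (i in 1:50) {
    N <- sample(2:40, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_pvalue(k, K, n, N),
                 hyper_tail_bruteforce(k, K, n, N), tolerance = 1e-12)
  }
  expect_error(hypergeom_pvalue(5, 4, 5, 10), "bounds")
})

test_that("tail probability is monotone decreasing in k", {
  for (K in c(3, 7)) {
    for (n in c(4, 9)) {
      p <- hypergeom_pvalue(0:min(K, n), K, n, 12)
      expect_true(all(diff(p) <= 1e-15))
    }
  }
})

test_that("Bonferroni adjustment uses the tested family and caps at 1", {
  enc <- make_encounters(list(e1 = c("A", "B")), list(e1 = c("x", "y")))
  pc <- build_pairs(enc)
  assoc <- enrich(pc, alpha = 0.05)
  m <- attr(assoc, "m")
  expect_equal(m, nrow(assoc))
  expect_equal(assoc$p_adj, pmin(1, m * assoc$p_raw))
  expect_equal(assoc$significant, assoc$p_adj < 0.05)
  # family = "all" widens m to the full grid
  assoc_all <- enrich(pc, family = "all")
  expect_equal(attr(assoc_all, "m"), length(pc$drugs) * length(pc$diagnoses))
})

test_that("strongly planted pairs are all significant", {
  cfg <- synthetic_config(n_encounters = 800, n_drugs = 8, n_diagnoses = 8,
                          n_blocks = 2, signal_prob = 1, noise_prob = 0,
                          n_unassociated_drugs = 0, seed = 5)
  co <- generate_cohort(cfg)
  assoc <- enrich(build_pairs(co$encounters))
  sig <- paste(assoc$drug_code, assoc$diagnosis_code)[assoc$significant]
  planted <- paste(co$truth$signal_pairs$drug_code,
                   co$truth$signal_pairs$diagnosis_code)
  expect_true(all(planted %in% sig))
  # and nothing off-block sneaks in
  expect_true(all(sig %in% planted))
})

test_that("family-wise false positives stay controlled on null cohorts", {
  fp <- 0L
  R <- 40L
  for (r in seq_len(R)) {
    co <- generate_cohort(synthetic_config(n_encounters = 500,
                                           n_drugs = 20, n_diagnoses = 30,
                                           signal_prob = 0,
                                           seed = 7000 + r))
    assoc <- enrich(build_pairs(co$encounters), alpha = 0.05)
    if (any(assoc$significant)) fp <- fp + 1L
  }
  expect_lte(fp / R, 0.05 + 3 * sqrt(0.05 * 0.95 / R))
})

test_that("significance matrix spans the cohort and counts match", {
  co <- generate_cohort(synthetic_config(n_encounters = 400, seed = 2))
  assoc <- enrich(build_pairs(co$encounters))
  m <- significance_matrix(assoc)
  # spans every drug/diagnosis observed in the cohort, not just tested pairs
  expect_equal(nrow(m),
               length(unique(co$encounters$drug_events$drug_code)))
  expect_equal(ncol(m),
               length(unique(co$encounters$diagnosis_events$diagnosis_code)))
  expect_equal(sum(m), sum(assoc$significant))
  expect_true(all(m %in% 0:1))
  # unassociated drugs keep all-zero rows
  unassoc <- intersect(names(co$truth$drug_block)[co$truth$drug_block == 0],
                       rownames(m))
  expect_true(all(rowSums(m[unassoc, , drop = FALSE]) == 0))
  # no significant pairs -> all-zero matrix on the full index
  assoc0 <- assoc
  assoc0$significant <- FALSE
  m0 <- significance_matrix(assoc0)
  expect_equal(dim(m0), dim(m))
  expect_equal(sum(m0), 0)
})
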