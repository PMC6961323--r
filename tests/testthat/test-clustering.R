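# binary matrix with two perfectly separated diagnosis blocks
two_block_binmat <- function(n_per_block = 10L, n_dx = 12L) {
  drugs <- paste0("d", seq_len(2 * n_per_block))
  dxs <- paste0("g", seq_len(2 * n_dx))
  m <- matrix(0L, length(drugs), length(dxs),
              dimnames = list(drugs, dxs))
  m[seq_len(n_per_block), seq_len(n_dx)] <- 1L
  m[n_per_block + seq_len(n_per_block), n_dx + seq_len(n_dx)] <- 1L
  m
}

test_that("k-means partition recovers two disjoint diagnosis blocks", {
  d <- distance_matrix(two_block_binmat())
  cl <- cluster_drugs(d, 2, seed = 1)
  truth <- rep(1:2, each = 10)
  expect_equal(mclust::adjustedRandIndex(cl$partition, truth), 1)
  # determinism under the same seed
  cl2 <- cluster_drugs(d, 2, seed = 1)
  expect_identical(cl$partition, cl2$partition)
  # partition is total with nonempty clusters
  expect_equal(sort(unique(cl$partition)), 1:2)
  expect_length(cl$partition, nrow(d))
})

test_that("k close to n yields singletons but keeps the partition total", {
  set.seed(4)
  m <- random_binmat(8, 15, p = 0.4)
  d <- distance_matrix(m)
  cl <- suppressWarnings(cluster_drugs(d, 7, seed = 2))
  expect_length(cl$partition, 8L)
  expect_equal(length(unique(cl$partition)), 7L)
  expect_true(any(table(cl$partition) == 1))
  expect_error(cluster_drugs(d, 8, seed = 2), "k <")
})

test_that("bootstrap stability is 1 on perfectly separable blocks", {
  d <- distance_matrix(two_block_binmat())
  s <- bootstrap_stability(d, 2, B = 10, seed = 3, n_init = 5)
  expect_equal(as.numeric(s), 1)
  expect_true(all(attr(s, "clusterwise") == 1))
  # determinism
  s2 <- bootstrap_stability(d, 2, B = 10, seed = 3, n_init = 5)
  expect_identical(as.numeric(s), as.numeric(s2))
  expect_error(bootstrap_stability(d, 20, B = 5), "smaller")
})

test_that("stability stays in [0, 1] on noisy data", {
  set.seed(17)
  m <- random_binmat(15, 20, p = 0.4)
  d <- distance_matrix(m)
  s <- as.numeric(bootstrap_stability(d, 3, B = 8, seed = 5, n_init = 3))
  expect_gte(s, 0)
  expect_lte(s, 1)
})

test_that("select_k returns the argmax with smallest-k tie-breaking", {
  d <- distance_matrix(two_block_binmat(n_per_block = 6))
  cfg <- clustering_config(k_min = 2, k_max = 2, B = 4, seed = 1,
                           n_init = 3)
  expect_equal(select_k(d, cfg)$k_best, 2L)
  # two-block structure maximizes stability at k = 2 over a range
  cfg <- clustering_config(k_min = 2, k_max = 5, B = 8, seed = 1,
                           n_init = 5)
  sel <- select_k(d, cfg)
  expect_equal(sel$k_best, 2L)
  expect_equal(nrow(sel$profile), 4L)
  # a flat profile falls back to the smallest candidate (first maximum)
  expect_equal(which.max(c(1, 1, 1)), 1L)
  cfg_bad <- clustering_config(k_min = 2, k_max = 50, B = 4, seed = 1)
  expect_error(select_k(d, cfg_bad), "k_max")
})

test_that("kernel sets honor the membership-share threshold", {
  m <- matrix(c(1, 0, 0,
                0, 1, 0,
                0, 0, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("d1", "d2", "d3"), c("a", "b", "c")))
  cl <- structure(list(partition = c(d1 = 1L, d2 = 1L, d3 = 2L), k = 2L),
                  class = "drug_clustering")
  union_k <- kernel_diagnoses(cl, m, min_share = 0)$kernel_sets
  expect_equal(sort(union_k[["1"]]), c("a", "b"))
  expect_equal(union_k[["2"]], character(0))  # no-association cluster
  inter_k <- kernel_diagnoses(cl, m, min_share = 1)$kernel_sets
  expect_equal(inter_k[["1"]], character(0))
})

test_that("cluster hierarchy merges the most-overlapping kernels first", {
  # hand-computed: d(1,2) = 1 - 2/4 = 0.5, d(1,3) = d(2,3) = 1
  kernels <- list(`1` = c("a", "b", "c"), `2` = c("a", "b", "d"),
                  `3` = c("x", "y"))
  hc <- cluster_hierarchy(kernels)
  expect_equal(hc$merge[1, ], c(-1L, -2L))
  expect_equal(hc$height[1], 0.5)
  # identical kernels merge at height 0
  hc0 <- cluster_hierarchy(list(`1` = "a", `2` = "a"))
  expect_equal(hc0$height, 0)
  # all-disjoint inputs: linkage choice cannot change the heights
  disj <- list(`1` = "a", `2` = "b", `3` = "c")
  expect_equal(cluster_hierarchy(disj, "single")$height,
               cluster_hierarchy(disj, "average")$height)
  expect_error(cluster_hierarchy(kernels[1]), "at least 2")
  # Newick export is parseable and keeps the leaves
  tr <- ape::read.tree(text = hierarchy_newick(hc))
  expect_setequal(tr$tip.label, names(kernels))
})

test_that("classical MDS embedding preserves coarse geometry", {
  # three mutually equidistant drugs embed as an equilateral triangle
  d <- matrix(1, 3, 3, dimnames = list(paste0("d", 1:3), paste0("d", 1:3)))
  diag(d) <- 0
  xy <- embed_2d(d)
  pd <- as.matrix(dist(xy))
  off <- pd[upper.tri(pd)]
  expect_true(max(off) - min(off) < 1e-9)

  # two tight blocks: between-block embedded distances dominate
  db <- distance_matrix(two_block_binmat())
  xy <- embed_2d(db)
  pd <- as.matrix(dist(xy))
  within <- c(pd[1:10, 1:10][upper.tri(pd[1:10, 1:10])],
              pd[11:20, 11:20][upper.tri(pd[11:20, 11:20])])
  between <- pd[1:10, 11:20]
  expect_gt(mean(between), mean(within))
  # duplicate profiles map to coincident coordinates
  expect_lt(max(dist(xy[1:10, ])), 1e-6)
  expect_error(embed_2d(d[1:2, 1:2]), "at least 3")
})
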