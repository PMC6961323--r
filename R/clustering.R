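#' Clustering configuration
#'
#' Bundles the tunable parameters of the drug-clustering stage. The
#' candidate range for the cluster count defaults to 10..50; bootstrap
#' resamples default to 100 with 10 k-means restarts per fit.
#'
#' @param k_min,k_max candidate cluster-count range.
#' @param B bootstrap resamples for stability estimation.
#' @param seed integer pipeline seed; per-stage seeds are derived from it.
#' @param n_init k-means restarts; the best within-cluster sum of squares
#'   is kept.
#' @param kernel_min_share minimum fraction of a cluster's drugs that must
#'   share a diagnosis for it to enter the cluster's kernel set (0 =
#'   union over members).
#' @return a `clustering_config` list.
#' @export
clustering_config <- function(k_min = 10L, k_max = 50L, B = 100L,
                              seed = 1L, n_init = 10L,
                              kernel_min_share = 0) {
  stopifnot(k_min >= 2, k_max >= k_min, B >= 2, n_init >= 1,
            kernel_min_share >= 0, kernel_min_share <= 1)
  structure(list(k_min = as.integer(k_min), k_max = as.integer(k_max),
                 B = as.integer(B), seed = as.integer(seed),
                 n_init = as.integer(n_init),
                 kernel_min_share = kernel_min_share),
            class = "clustering_config")
}

# k-means over the rows of a feature matrix with deterministic restarts.
# Initial centers are drawn from the distinct rows so duplicated profiles
# cannot produce empty clusters. When fewer distinct rows than k exist the
# partition falls back to a deterministic split of the duplicate groups.
kmeans_partition <- function(feat, k, seed, n_init, warn = TRUE) {
  n <- nrow(feat)
  key <- apply(feat, 1L, paste, collapse = "\r")
  uniq_keys <- unique(key)
  u <- length(uniq_keys)
  if (u < k) {
    if (warn) {
      warning("fewer distinct drug profiles (", u, ") than clusters (", k,
              "); using a deterministic split")
    }
    return(split_to_k(match(key, uniq_keys), k))
  }
  set.seed(seed)
  uniq_rows <- feat[!duplicated(key), , drop = FALSE]
  best <- NULL
  best_ss <- Inf
  for (i in seq_len(n_init)) {
    centers <- uniq_rows[kmeanspp_seed(uniq_rows, k), , drop = FALSE]
    km <- tryCatch(
      suppressWarnings(stats::kmeans(feat, centers = centers,
                                     iter.max = 100L)),
      error = function(e) NULL)
    if (!is.null(km) && km$tot.withinss < best_ss &&
        length(unique(km$cluster)) == k) {
      best <- km$cluster
      best_ss <- km$tot.withinss
    }
  }
  if (is.null(best)) {
    return(split_to_k(match(key, uniq_keys), k))
  }
  best
}

# k-means++ seeding over distinct rows: first center uniform, subsequent
# centers drawn with probability proportional to squared distance to the
# nearest chosen center. Returns row indices into `rows`.
kmeanspp_seed <- function(rows, k) {
  u <- nrow(rows)
  centers <- integer(k)
  centers[1] <- sample.int(u, 1L)
  d2 <- rowSums(sweep(rows, 2, rows[centers[1], ])^2)
  for (j in seq_len(k - 1L)) {
    prob <- if (sum(d2) > 0) d2 else rep(1, u)
    centers[j + 1L] <- sample.int(u, 1L, prob = prob)
    d2 <- pmin(d2, rowSums(sweep(rows, 2, rows[centers[j + 1L], ])^2))
  }
  centers
}

# Deterministically refine a grouping into exactly k nonempty clusters by
# repeatedly halving the largest group (members in index order).
split_to_k <- function(grp, k) {
  grp <- as.integer(factor(grp))
  while (length(unique(grp)) < k) {
    sizes <- table(grp)
    big <- as.integer(names(sizes)[which.max(sizes)])
    members <- which(grp == big)
    new_id <- max(grp) + 1L
    grp[members[seq_len(floor(length(members) / 2))]] <- new_id
  }
  # merge smallest groups if somehow above k (cannot happen via halving)
  as.integer(factor(grp))
}

#' Partition drugs by k-means on the distance profile
#'
#' Each drug is represented by its row of the Jaccard distance matrix
#' (its distances to all drugs) and the rows are partitioned with k-means
#' using `n_init` deterministic restarts, keeping the fit with the lowest
#' within-cluster sum of squares. With fewer distinct profiles than `k`
#' (e.g. an all-zero significance matrix) a warning is issued and the
#' duplicate groups are split deterministically.
#'
#' @param distmat symmetric drug-drug distance matrix from
#'   [distance_matrix()].
#' @param k number of clusters, `2 <= k < nrow(distmat)`.
#' @param seed integer seed; identical inputs and seed give an identical
#'   partition.
#' @param n_init number of k-means restarts.
#' @return object of class `drug_clustering`: list with `partition` (named
#'   integer vector drug -> cluster id in 1..k), `k`, and empty slots for
#'   `stability` and `kernel_sets` filled by later stages.
#' @export
cluster_drugs <- function(distmat, k, seed = 1L, n_init = 10L) {
  n <- nrow(distmat)
  if (k < 2L || k >= n) stop("need 2 <= k < number of drugs")
  part <- kmeans_partition(distmat, k, derive_seed(seed, "kmeans"), n_init)
  part <- as.integer(factor(part))  # contiguous ids 1..k
  names(part) <- rownames(distmat)
  structure(list(partition = part, k = k, stability = NULL,
                 kernel_sets = NULL, seed = seed),
            class = "drug_clustering")
}

#' @export
print.drug_clustering <- function(x, ...) {
  cat("drug_clustering:", length(x$partition), "drugs in", x$k,
      "clusters\n")
  print(table(cluster = x$partition))
  invisible(x)
}

#' Bootstrap cluster-wise stability (mean Jaccard index)
#'
#' Estimates how reproducible a k-cluster partition is: the drugs are
#' clustered once on the full data (the reference), then `B` bootstrap
#' resamples of the drugs (with replacement) are re-clustered, and each
#' reference cluster is scored by the maximum Jaccard overlap between its
#' membership (restricted to the drugs present in the resample) and any
#' bootstrap cluster. The returned value is the mean over reference
#' clusters and resamples; 1 means every cluster is recovered exactly in
#' every resample. Reference clusters with no member drawn into a resample
#' are excluded from that resample's mean.
#'
#' @inheritParams cluster_drugs
#' @param B number of bootstrap resamples (>= 2).
#' @return scalar mean Jaccard stability in \[0, 1\], with the per-cluster
#'   mean stabilities as attribute `"clusterwise"`.
#' @export
bootstrap_stability <- function(distmat, k, B = 100L, seed = 1L,
                                n_init = 10L) {
  n <- nrow(distmat)
  if (k >= n) stop("k must be smaller than the number of drugs")
  if (B < 2L) stop("need at least 2 bootstrap resamples")
  ref <- kmeans_partition(distmat, k, derive_seed(seed, "kmeans"), n_init,
                          warn = FALSE)
  ref_members <- split(seq_len(n), ref)

  per_cluster <- matrix(NA_real_, length(ref_members), B)
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, paste0("bootstrap-", b)))
    idx <- sample.int(n, n, replace = TRUE)
    boot_part <- kmeans_partition(distmat[idx, , drop = FALSE], k,
                                  derive_seed(seed, paste0("boot-km-", b)),
                                  n_init, warn = FALSE)
    boot_members <- lapply(split(seq_along(idx), boot_part),
                           function(i) unique(idx[i]))
    present <- unique(idx)
    for (ci in seq_along(ref_members)) {
      mem <- intersect(ref_members[[ci]], present)
      if (length(mem) == 0L) next
      per_cluster[ci, b] <- max(vapply(boot_members, jaccard_overlap,
                                       numeric(1), b = mem))
    }
  }
  clusterwise <- rowMeans(per_cluster, na.rm = TRUE)
  out <- mean(per_cluster, na.rm = TRUE)
  attr(out, "clusterwise") <- clusterwise
  out
}

#' Select the number of clusters by bootstrap stability
#'
#' Evaluates [bootstrap_stability()] for every candidate `k` in
#' `[k_min, k_max]` and returns the `k` with the highest mean Jaccard
#' stability, breaking ties toward the smallest `k`.
#'
#' @param distmat drug-drug distance matrix.
#' @param config a [clustering_config()].
#' @return list with `k_best` and `profile`, a data.frame of `k` and
#'   `stability`.
#' @export
select_k <- function(distmat, config = clustering_config()) {
  stopifnot(inherits(config, "clustering_config"))
  n <- nrow(distmat)
  if (config$k_max >= n) stop("k_max must be smaller than the number of drugs")
  ks <- seq(config$k_min, config$k_max)
  stab <- vapply(ks, function(k) {
    as.numeric(bootstrap_stability(distmat, k, B = config$B,
                                   seed = derive_seed(config$seed,
                                                      paste0("select-k-", k)),
                                   n_init = config$n_init))
  }, numeric(1))
  profile <- data.frame(k = ks, stability = stab)
  k_best <- ks[which.max(stab)]  # which.max returns first max: smallest k
  list(k_best = k_best, profile = profile)
}

#' Kernel diagnosis sets of drug clusters
#'
#' The kernel of a cluster is the set of diagnoses significantly
#' associated with at least `min_share` of its member drugs. With
#' `min_share = 0` the kernel is the union of the members' significant
#' diagnosis sets; with `min_share = 1` their intersection. A cluster of
#' drugs with no significant association has an empty kernel.
#'
#' @param clustering a [cluster_drugs()] result.
#' @param binmat binary significant-association matrix sharing the drug
#'   index with `clustering`.
#' @param min_share fraction in \[0, 1\].
#' @return the `clustering` with `kernel_sets` filled: a named list,
#'   cluster id -> character vector of diagnosis codes.
#' @export
kernel_diagnoses <- function(clustering, binmat, min_share = 0) {
  stopifnot(inherits(clustering, "drug_clustering"),
            min_share >= 0, min_share <= 1)
  part <- clustering$partition
  if (!all(names(part) %in% rownames(binmat))) {
    stop("clustering and binary matrix must share the drug index")
  }
  kernels <- lapply(split(names(part), part), function(members) {
    share <- colMeans(binmat[members, , drop = FALSE])
    thr <- if (min_share == 0) share > 0 else share >= min_share & share > 0
    colnames(binmat)[thr]
  })
  clustering$kernel_sets <- kernels
  clustering
}

#' Hierarchy of drug clusters from kernel-set distances
#'
#' Agglomerative hierarchical clustering of the drug clusters themselves,
#' using the Jaccard distance between their kernel diagnosis sets, so
#' clusters treating overlapping clinical conditions merge early.
#'
#' @param kernel_sets named list of diagnosis-code sets (e.g.
#'   `clustering$kernel_sets` after [kernel_diagnoses()]).
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return an `hclust` tree whose labels are the cluster ids.
#' @export
cluster_hierarchy <- function(kernel_sets, linkage = "average") {
  if (length(kernel_sets) < 2L) stop("need at least 2 clusters")
  ids <- names(kernel_sets)
  m <- length(ids)
  d <- matrix(0, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      d[i, j] <- d[j, i] <- jaccard_distance(kernel_sets[[i]],
                                             kernel_sets[[j]])
    }
  }
  stats::hclust(stats::as.dist(d), method = linkage)
}

#' Export a cluster hierarchy as a Newick string
#'
#' @param hc an `hclust` tree from [cluster_hierarchy()].
#' @return single-element character vector in Newick format.
#' @export
hierarchy_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Classical multidimensional scaling of the drug-drug distances
#'
#' Principal-coordinates embedding: the top-2 eigencomponents of the
#' double-centered squared distance matrix, giving a planar map in which
#' drugs with similar significant-diagnosis sets lie close together.
#' Deterministic up to axis sign and rotation among tied eigenvalues.
#'
#' @param distmat symmetric drug-drug distance matrix, at least 3 x 3.
#' @return numeric matrix (drugs x 2) of coordinates, drug codes as
#'   rownames.
#' @export
embed_2d <- function(distmat) {
  if (nrow(distmat) < 3L) stop("need at least 3 drugs to embed")
  coords <- stats::cmdscale(stats::as.dist(distmat), k = 2)
  if (ncol(coords) < 2L) {
    coords <- cbind(coords,
                    matrix(0, nrow(coords), 2L - ncol(coords)))
  }
  colnames(coords) <- c("mds1", "mds2")
  rownames(coords) <- rownames(distmat)
  coords
}
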