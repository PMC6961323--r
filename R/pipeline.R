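#' Run the full drug-safety pipeline
#'
#' Orchestrates the stages end-to-end on one cohort: pair counting and
#' hypergeometric enrichment with Bonferroni control, the binary
#' significant-association matrix, Jaccard drug-drug distances,
#' bootstrap-stability selection of the cluster count (or a fixed `k`),
#' k-means drug clustering, kernel diagnosis sets, the inter-cluster
#' hierarchy, 2-D embedding, and — when labels are supplied — per-drug
#' safety levels and the per-cluster safety summary. All intermediate
#' artifacts are written as delimited text under `out_dir` together with a
#' run manifest recording parameters, seed and artifact list. Degenerate
#' cohorts (no significant pair at all) run through without error: all
#' drugs share one distance profile and the partition degrades to a
#' deterministic split.
#'
#' @param encounters an [encounter_table()].
#' @param labels optional `drug_label_table` for the safety stages.
#' @param alpha Bonferroni-adjusted significance threshold.
#' @param family tested-family definition, see [enrich()].
#' @param k fixed cluster count; `NULL` selects it by [select_k()].
#' @param config a [clustering_config()]; its seed drives every stochastic
#'   stage.
#' @param out_dir output directory; `NULL` skips writing.
#' @return list with `association_table`, `significance_matrix`,
#'   `distance_matrix`, `k`, `stability_profile`, `clustering`,
#'   `hierarchy`, `embedding`, `safety` (per-drug levels and
#'   `cluster_safety_table`, or `NULL`), and `manifest`.
#' @export
run_pipeline <- function(encounters, labels = NULL, alpha = 0.05,
                         family = "nonzero", k = NULL,
                         config = clustering_config(),
                         out_dir = NULL) {
  stage <- "enrichment"
  res <- tryCatch({
    pairs <- build_pairs(encounters)
    assoc <- enrich(pairs, alpha = alpha, family = family)
    binmat <- significance_matrix(assoc)

    stage <- "distance"
    distmat <- distance_matrix(binmat)

    stage <- "clustering"
    profile <- NULL
    if (is.null(k)) {
      sel <- select_k(distmat, config)
      k <- sel$k_best
      profile <- sel$profile
    }
    clustering <- suppressWarnings(
      cluster_drugs(distmat, k, seed = config$seed,
                    n_init = config$n_init))
    clustering <- kernel_diagnoses(clustering, binmat,
                                   min_share = config$kernel_min_share)
    hier <- if (clustering$k >= 2)
      cluster_hierarchy(clustering$kernel_sets) else NULL
    coords <- if (nrow(distmat) >= 3) suppressWarnings(embed_2d(distmat))
      else NULL

    stage <- "safety"
    safety <- NULL
    if (!is.null(labels)) {
      lv <- safety_levels(labels)
      safety <- list(levels = lv,
                     cluster_table = cluster_safety(clustering, lv),
                     distribution = safety_distribution(clustering, lv))
    }

    list(association_table = assoc, significance_matrix = binmat,
         distance_matrix = distmat, k = k, stability_profile = profile,
         clustering = clustering, hierarchy = hier, embedding = coords,
         safety = safety)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  manifest <- list(
    alpha = alpha, family = family, k = res$k, seed = config$seed,
    n_drugs = nrow(res$distance_matrix),
    n_diagnoses = ncol(res$significance_matrix),
    n_significant = sum(res$association_table$significant),
    artifacts = character(0)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    art <- function(name, writer) {
      path <- file.path(out_dir, name)
      writer(path)
      manifest$artifacts <<- c(manifest$artifacts, name)
    }
    art("associations.tsv", function(p) write_table(res$association_table, p))
    art("significance_matrix.tsv",
        function(p) write_table(res$significance_matrix, p))
    art("distance_matrix.tsv",
        function(p) write_table(res$distance_matrix, p))
    art("partition.tsv", function(p)
      write_table(data.frame(drug_code = names(res$clustering$partition),
                             cluster_id = res$clustering$partition), p))
    if (!is.null(res$stability_profile)) {
      art("stability_profile.tsv",
          function(p) write_table(res$stability_profile, p))
    }
    kern <- do.call(rbind, lapply(names(res$clustering$kernel_sets),
      function(cid) if (length(res$clustering$kernel_sets[[cid]]) > 0)
        data.frame(cluster_id = cid,
                   diagnosis_code = res$clustering$kernel_sets[[cid]])))
    if (!is.null(kern)) {
      art("kernel_sets.tsv", function(p) write_table(kern, p))
    }
    if (!is.null(res$hierarchy)) {
      art("cluster_hierarchy.nwk", function(p)
        writeLines(hierarchy_newick(res$hierarchy), p))
    }
    if (!is.null(res$embedding)) {
      art("embedding.tsv", function(p) write_table(res$embedding, p))
    }
    if (!is.null(res$safety)) {
      art("safety_levels.tsv", function(p) write_table(res$safety$levels, p))
      art("cluster_safety.tsv",
          function(p) write_table(res$safety$cluster_table, p))
    }
    manifest_df <- data.frame(
      key = c("alpha", "family", "k", "seed", "n_drugs", "n_diagnoses",
              "n_significant", "artifacts"),
      value = c(alpha, family, res$k, config$seed, manifest$n_drugs,
                manifest$n_diagnoses, manifest$n_significant,
                paste(manifest$artifacts, collapse = ";")))
    write_table(manifest_df, file.path(out_dir, "manifest.tsv"))
    manifest$artifacts <- c(manifest$artifacts, "manifest.tsv")
  }

  res$manifest <- manifest
  res
}
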