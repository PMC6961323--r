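#' Per-diagnosis incidence in per mille of encounters
#'
#' @param encounters an [encounter_table()].
#' @return named numeric vector: for each diagnosis, 1000 times the number
#'   of encounters carrying it divided by the total encounter count.
#' @export
incidence <- function(encounters) {
  stopifnot(inherits(encounters, "encounter_table"))
  total <- length(encounters$encounters)
  if (total == 0L) stop("encounter table is empty")
  counts <- table(encounters$diagnosis_events$diagnosis_code)
  stats::setNames(1000 * as.numeric(counts) / total, names(counts))
}

sig_sets <- function(assoc, by = c("diagnosis", "drug")) {
  by <- match.arg(by)
  sig <- assoc[assoc$significant, , drop = FALSE]
  if (by == "diagnosis") {
    split(sig$drug_code, sig$diagnosis_code)
  } else {
    split(sig$diagnosis_code, sig$drug_code)
  }
}

#' Align two cohorts' significant associations by diagnosis
#'
#' For every diagnosis seen in either cohort, reports its presence and
#' incidence in each cohort and the number of drugs significantly
#' associated with it in cohort A, in cohort B, and in both (the overlap
#' of the two significant drug sets).
#'
#' @param assoc_a,assoc_b association tables ([enrich()]) for the two
#'   cohorts.
#' @param enc_a,enc_b the matching encounter tables.
#' @return data.frame with one row per diagnosis in the union:
#'   `diagnosis_code`, `present_in_A`, `present_in_B`, `incidence_A`,
#'   `incidence_B` (per mille), `n_assoc_drugs_A`, `n_assoc_drugs_B`,
#'   `n_assoc_overlap`.
#' @export
align_by_diagnosis <- function(assoc_a, assoc_b, enc_a, enc_b) {
  inc_a <- incidence(enc_a)
  inc_b <- incidence(enc_b)
  sets_a <- sig_sets(assoc_a, "diagnosis")
  sets_b <- sig_sets(assoc_b, "diagnosis")
  dx_a <- unique(enc_a$diagnosis_events$diagnosis_code)
  dx_b <- unique(enc_b$diagnosis_events$diagnosis_code)
  all_dx <- sort(union(dx_a, dx_b))

  out <- data.frame(
    diagnosis_code = all_dx,
    present_in_A = all_dx %in% dx_a,
    present_in_B = all_dx %in% dx_b,
    incidence_A = ifelse(all_dx %in% names(inc_a), inc_a[all_dx], 0),
    incidence_B = ifelse(all_dx %in% names(inc_b), inc_b[all_dx], 0),
    n_assoc_drugs_A = vapply(all_dx, function(g)
      length(sets_a[[g]]), integer(1)),
    n_assoc_drugs_B = vapply(all_dx, function(g)
      length(sets_b[[g]]), integer(1)),
    n_assoc_overlap = vapply(all_dx, function(g)
      length(intersect(sets_a[[g]], sets_b[[g]])), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

drug_volume <- function(encounters) {
  table(encounters$drug_events$drug_code)
}

#' Align two cohorts' significant associations by drug
#'
#' Mirror of [align_by_diagnosis()] with roles swapped: one row per drug
#' in the union of the cohorts, with deduplicated use volumes (number of
#' encounters in which the drug was given) and the per-drug counts of
#' significantly associated diagnoses in each cohort and their overlap.
#'
#' @inheritParams align_by_diagnosis
#' @return data.frame with `drug_code`, `present_in_A`, `present_in_B`,
#'   `use_volume_A`, `use_volume_B`, `n_assoc_dx_A`, `n_assoc_dx_B`,
#'   `n_assoc_overlap`.
#' @export
align_by_drug <- function(assoc_a, assoc_b, enc_a, enc_b) {
  vol_a <- drug_volume(enc_a)
  vol_b <- drug_volume(enc_b)
  sets_a <- sig_sets(assoc_a, "drug")
  sets_b <- sig_sets(assoc_b, "drug")
  d_a <- unique(enc_a$drug_events$drug_code)
  d_b <- unique(enc_b$drug_events$drug_code)
  all_d <- sort(union(d_a, d_b))

  data.frame(
    drug_code = all_d,
    present_in_A = all_d %in% d_a,
    present_in_B = all_d %in% d_b,
    use_volume_A = ifelse(all_d %in% names(vol_a),
                          as.numeric(vol_a[all_d]), 0),
    use_volume_B = ifelse(all_d %in% names(vol_b),
                          as.numeric(vol_b[all_d]), 0),
    n_assoc_dx_A = vapply(all_d, function(d)
      length(sets_a[[d]]), integer(1)),
    n_assoc_dx_B = vapply(all_d, function(d)
      length(sets_b[[d]]), integer(1)),
    n_assoc_overlap = vapply(all_d, function(d)
      length(intersect(sets_a[[d]], sets_b[[d]])), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Group alignment rows by hierarchical clustering
#'
#' Clusters the rows of an alignment table into `n_groups` groups with
#' average-linkage agglomerative clustering on standardized features
#' (presence flags as 0/1; counts and volumes log1p-transformed then
#' z-scored), cutting the dendrogram at `n_groups`. This is the mechanism
#' behind dividing a disease spectrum or drug list into interpretable
#' groups.
#'
#' @param table alignment table from [align_by_diagnosis()] or
#'   [align_by_drug()].
#' @param n_groups number of groups (>= 2).
#' @param features character vector of column names to cluster on;
#'   defaults to all logical and numeric columns.
#' @return integer vector of group labels (1..n_groups), one per row.
#' @export
group_alignment <- function(table, n_groups, features = NULL) {
  if (n_groups < 2L) stop("n_groups must be >= 2")
  if (n_groups > nrow(table)) stop("n_groups exceeds number of rows")
  if (is.null(features)) {
    features <- names(table)[vapply(table, function(x)
      is.numeric(x) || is.logical(x), logical(1))]
  }
  feat <- as.matrix(as.data.frame(lapply(table[, features, drop = FALSE],
                                         as.numeric)))
  count_like <- apply(feat, 2, function(x) any(x > 1))
  feat[, count_like] <- log1p(feat[, count_like])
  sds <- apply(feat, 2, stats::sd)
  feat <- scale(feat, center = TRUE,
                scale = ifelse(sds > 0, sds, 1))
  hc <- stats::hclust(stats::dist(feat), method = "average")
  as.integer(stats::cutree(hc, k = n_groups))
}

#' Category composition of groups
#'
#' For each group of aligned rows, the percentage falling in each coding
#' category (e.g. ICD-10 chapter for diagnoses, first-level ATC class for
#' drugs). Codes absent from the map are tallied under `"unmapped"`.
#'
#' @param groups integer group labels, one per code.
#' @param codes character vector of codes (same length as `groups`).
#' @param category_map named character vector or two-column data.frame
#'   mapping code -> category.
#' @return numeric matrix (groups x categories) of percentages; each row
#'   sums to 100.
#' @export
category_composition <- function(groups, codes, category_map) {
  if (is.data.frame(category_map)) {
    category_map <- stats::setNames(as.character(category_map[[2]]),
                                    category_map[[1]])
  }
  cat_of <- unname(category_map[codes])
  cat_of[is.na(cat_of)] <- "unmapped"
  tab <- table(group = groups, category = cat_of)
  100 * sweep(unclass(tab), 1, rowSums(tab), "/")
}
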