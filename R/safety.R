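#' Map a pediatric labeling statement to the 0-5 safety level
#'
#' The safety level encodes the youngest pediatric population a drug's
#' labeling covers:
#'
#' * 5 — preterm newborn infants
#' * 4 — full-term newborns (0 to 28 days)
#' * 3 — infants and toddlers (>28 days to 23 months)
#' * 2 — children (2 to 11 years), or a pediatric indication without a
#'   specific age statement
#' * 1 — adolescents only (12 to 18 years)
#' * 0 — no pediatric labeling, safety and efficacy not established, or
#'   contraindicated / not applicable in children
#'
#' When a numeric minimum labeled age is available it takes precedence
#' over the statement class and is binned on these boundaries (a negative
#' age denotes a gestational/preterm indication; a minimum age above 18
#' years maps to level 0 with a warning). A contraindication always
#' dominates: such drugs are level 0 regardless of any age range.
#'
#' @param label one row of a `drug_label_table` (data.frame with
#'   `label_statement_class` and optional `min_age_value`,
#'   `min_age_unit`), or a statement class string.
#' @param min_age_value,min_age_unit numeric minimum labeled age and its
#'   unit (`days`, `months`, `years`), used when `label` is a string.
#' @return integer safety level in 0..5 with the originating statement
#'   class as attribute `"provenance"`.
#' @export
assign_safety_level <- function(label, min_age_value = NA_real_,
                                min_age_unit = NA_character_) {
  if (is.data.frame(label)) {
    stopifnot(nrow(label) == 1L)
    cls <- label$label_statement_class
    if ("min_age_value" %in% names(label)) min_age_value <- label$min_age_value
    if ("min_age_unit" %in% names(label)) min_age_unit <- label$min_age_unit
  } else {
    cls <- as.character(label)
  }
  if (!cls %in% label_classes) {
    stop(sprintf("unknown label statement class '%s'", cls))
  }
  level <- if (cls %in% c("contraindicated", "not_established",
                          "no_pediatric_labeling")) {
    0L
  } else if (!is.na(min_age_value) && !is.na(min_age_unit)) {
    age_to_level(min_age_value, min_age_unit)
  } else {
    switch(cls,
           preterm = 5L, full_term_newborn = 4L, infant_toddler = 3L,
           child = 2L, child_no_age = 2L, adolescent = 1L)
  }
  structure(level, provenance = cls)
}

age_to_level <- function(value, unit) {
  yrs <- age_in_years(value, unit)
  if (yrs < 0) 5L
  else if (yrs <= 28 / 365.25) 4L
  else if (yrs < 2) 3L
  else if (yrs < 12) 2L
  else if (yrs <= 18) 1L
  else {
    warning("minimum labeled age above 18 years; treating as no pediatric labeling")
    0L
  }
}

#' Safety levels for every drug in a label table
#'
#' @param labels a `drug_label_table` from [read_drug_labels()] or
#'   [drug_label_table()].
#' @return data.frame with `drug_code`, `safety_level`, `provenance`.
#' @export
safety_levels <- function(labels) {
  stopifnot(is.data.frame(labels))
  lv <- lapply(seq_len(nrow(labels)), function(i)
    assign_safety_level(labels[i, , drop = FALSE]))
  data.frame(drug_code = labels$drug_code,
             safety_level = vapply(lv, as.integer, integer(1)),
             provenance = vapply(lv, attr, character(1), "provenance"),
             stringsAsFactors = FALSE)
}

#' Per-cluster pediatric safety summary
#'
#' Aggregates drug safety levels over a drug clustering: per cluster the
#' arithmetic mean level, the sample (n-1) standard deviation (0 for
#' singleton clusters), and the per-level counts.
#'
#' @param clustering a [cluster_drugs()] result.
#' @param levels data.frame from [safety_levels()], or a named vector
#'   drug_code -> level. Every clustered drug must have a level.
#' @return `cluster_safety_table` data.frame: `cluster_id`, `n_drugs`,
#'   `mean_level`, `sd_level`, and `n_level_0` .. `n_level_5` columns.
#' @export
cluster_safety <- function(clustering, levels) {
  lv <- as_level_vector(levels)
  part <- clustering$partition
  missing <- setdiff(names(part), names(lv))
  if (length(missing) > 0) {
    stop(sprintf("drugs missing a safety level: %s",
                 paste(missing, collapse = ", ")))
  }
  rows <- lapply(sort(unique(part)), function(cid) {
    vals <- lv[names(part)[part == cid]]
    counts <- tabulate(vals + 1L, nbins = 6L)
    data.frame(cluster_id = cid, n_drugs = length(vals),
               mean_level = mean(vals),
               sd_level = if (length(vals) > 1L) stats::sd(vals) else 0,
               t(stats::setNames(counts, paste0("n_level_", 0:5))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cluster_safety_table", "data.frame")
  out
}

#' Per-cluster distribution of safety levels
#'
#' @inheritParams cluster_safety
#' @return numeric matrix (clusters x levels 0..5) of within-cluster
#'   proportions; rows sum to 1.
#' @export
safety_distribution <- function(clustering, levels) {
  tab <- cluster_safety(clustering, levels)
  counts <- as.matrix(tab[, paste0("n_level_", 0:5)])
  props <- counts / tab$n_drugs
  dimnames(props) <- list(tab$cluster_id, paste0("level_", 0:5))
  props
}

as_level_vector <- function(levels) {
  if (is.data.frame(levels)) {
    stats::setNames(as.integer(levels$safety_level), levels$drug_code)
  } else {
    v <- as.integer(levels)
    names(v) <- names(levels)
    v
  }
}
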