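#' Configuration for the synthetic EMR cohort generator
#'
#' The generator emulates inpatient encounters with block-structured
#' drug-diagnosis co-occurrence: drugs and diagnoses are partitioned into
#' `n_blocks` clinical-condition blocks plus a pool of unassociated drugs
#' that only ever appear as background. Each encounter belongs to one
#' block; its diagnoses come from the block's diagnosis pool (with an
#' occasional uniform background diagnosis at rate `noise_prob`), and each
#' drug slot draws from the block's drug pool with probability
#' `signal_prob`, otherwise uniformly from all drugs. Event counts per
#' encounter are Poisson. `signal_prob = 0` gives a null cohort in which
#' drugs are independent of diagnoses.
#'
#' @param n_encounters,n_drugs,n_diagnoses cohort dimensions.
#' @param n_blocks number of planted condition blocks.
#' @param mean_drugs,mean_diagnoses Poisson means for events per
#'   encounter.
#' @param signal_prob probability a drug slot is drawn from the
#'   encounter's block pool.
#' @param noise_prob probability a diagnosis slot is uniform background
#'   rather than from the block pool.
#' @param n_unassociated_drugs drugs never tied to any block.
#' @param label_level_probs length-6 probability vector over safety
#'   levels 0..5 for the label generator.
#' @param seed integer seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_encounters = 2000L, n_drugs = 50L,
                             n_diagnoses = 80L, n_blocks = 5L,
                             mean_drugs = 3, mean_diagnoses = 3,
                             signal_prob = 0.9, noise_prob = 0.05,
                             n_unassociated_drugs = 5L,
                             label_level_probs = c(0.43, 0.09, 0.25,
                                                   0.12, 0.06, 0.05),
                             seed = 1L) {
  stopifnot(n_blocks >= 1, n_unassociated_drugs >= 0,
            n_unassociated_drugs < n_drugs,
            n_drugs - n_unassociated_drugs >= n_blocks,
            n_diagnoses >= n_blocks,
            signal_prob >= 0, signal_prob <= 1,
            noise_prob >= 0, noise_prob <= 1,
            length(label_level_probs) == 6L,
            all(label_level_probs >= 0), sum(label_level_probs) > 0)
  structure(list(n_encounters = as.integer(n_encounters),
                 n_drugs = as.integer(n_drugs),
                 n_diagnoses = as.integer(n_diagnoses),
                 n_blocks = as.integer(n_blocks),
                 mean_drugs = mean_drugs, mean_diagnoses = mean_diagnoses,
                 signal_prob = signal_prob, noise_prob = noise_prob,
                 n_unassociated_drugs = as.integer(n_unassociated_drugs),
                 label_level_probs = label_level_probs / sum(label_level_probs),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Preset generator configurations
#'
#' `"strong"`: 5 blocks, 100 drugs including 10 unassociated, 150
#' diagnoses, 5000 encounters, `signal_prob = 0.95` — clustering should
#' recover the planted blocks essentially perfectly. `"null"`: 50 drugs,
#' 80 diagnoses, 2000 encounters, `signal_prob = 0` — no true
#' drug-diagnosis association exists, so any significant pair is a false
#' positive. `"weak"`: as strong but `signal_prob = 0.5`.
#'
#' @param preset one of `"strong"`, `"null"`, `"weak"`.
#' @param seed integer seed.
#' @return a [synthetic_config()].
#' @export
synthetic_preset <- function(preset = c("strong", "null", "weak"),
                             seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
         strong = synthetic_config(n_encounters = 5000L, n_drugs = 100L,
                                   n_diagnoses = 150L, n_blocks = 5L,
                                   signal_prob = 0.95,
                                   n_unassociated_drugs = 10L, seed = seed),
         weak = synthetic_config(n_encounters = 5000L, n_drugs = 100L,
                                 n_diagnoses = 150L, n_blocks = 5L,
                                 signal_prob = 0.5,
                                 n_unassociated_drugs = 10L, seed = seed),
         null = synthetic_config(n_encounters = 2000L, n_drugs = 50L,
                                 n_diagnoses = 80L, n_blocks = 5L,
                                 signal_prob = 0, seed = seed))
}

#' Generate a synthetic EMR cohort with planted block structure
#'
#' @param config a [synthetic_config()].
#' @return list with `encounters` (an [encounter_table()]) and `truth`, a
#'   list holding `drug_block` (named vector; `0` marks unassociated
#'   drugs), `diagnosis_block`, and `signal_pairs` (data.frame of planted
#'   drug-diagnosis pairs). Deterministic under the config seed.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, "cohort"))

  pad <- function(prefix, i, n) sprintf("%s%0*d", prefix,
                                        nchar(as.character(n)), i)
  drugs <- vapply(seq_len(config$n_drugs), pad, character(1),
                  prefix = "D", n = config$n_drugs)
  dxs <- vapply(seq_len(config$n_diagnoses), pad, character(1),
                prefix = "G", n = config$n_diagnoses)

  # contiguous block assignment: first n_assoc drugs split evenly,
  # trailing drugs form the unassociated pool (block 0)
  n_assoc <- config$n_drugs - config$n_unassociated_drugs
  drug_block <- sort(rep(seq_len(config$n_blocks), length.out = n_assoc))
  drug_block <- c(drug_block, rep(0L, config$n_unassociated_drugs))
  names(drug_block) <- drugs
  dx_block <- sort(rep(seq_len(config$n_blocks),
                       length.out = config$n_diagnoses))
  names(dx_block) <- dxs

  drug_pools <- split(drugs, drug_block)
  dx_pools <- split(dxs, dx_block)

  enc_ids <- vapply(seq_len(config$n_encounters), pad, character(1),
                    prefix = "E", n = config$n_encounters)
  blocks <- sample.int(config$n_blocks, config$n_encounters, replace = TRUE)
  n_drug_ev <- stats::rpois(config$n_encounters, config$mean_drugs)
  n_dx_ev <- stats::rpois(config$n_encounters, config$mean_diagnoses)

  # vectorised event sampling: one slot per event, block draws grouped
  sample_events <- function(n_ev, pool_prob, pools, universe) {
    enc_rep <- rep.int(enc_ids, n_ev)
    block_rep <- rep.int(blocks, n_ev)
    n_tot <- length(enc_rep)
    codes <- character(n_tot)
    from_pool <- stats::runif(n_tot) < pool_prob
    if (any(!from_pool)) {
      codes[!from_pool] <- sample(universe, sum(!from_pool), replace = TRUE)
    }
    for (b in seq_len(config$n_blocks)) {
      sel <- from_pool & block_rep == b
      if (any(sel)) {
        codes[sel] <- sample(pools[[as.character(b)]], sum(sel),
                             replace = TRUE)
      }
    }
    list(encounter_id = enc_rep, code = codes)
  }

  dx_ev <- sample_events(n_dx_ev, 1 - config$noise_prob, dx_pools, dxs)
  drug_ev <- sample_events(n_drug_ev, config$signal_prob, drug_pools, drugs)
  dx_rows <- data.frame(encounter_id = dx_ev$encounter_id,
                        diagnosis_code = dx_ev$code)
  drug_rows <- data.frame(encounter_id = drug_ev$encounter_id,
                          drug_code = drug_ev$code)

  signal_pairs <- do.call(rbind, lapply(seq_len(config$n_blocks),
    function(b) expand.grid(drug_code = drug_pools[[as.character(b)]],
                            diagnosis_code = dx_pools[[as.character(b)]],
                            stringsAsFactors = FALSE)))

  enc <- encounter_table(drug_rows, dx_rows, encounter_ids = enc_ids)
  list(encounters = enc,
       truth = list(drug_block = drug_block, diagnosis_block = dx_block,
                    signal_pairs = signal_pairs))
}

#' Generate a synthetic pediatric label table
#'
#' Assigns each drug a labeling statement class drawn so that the induced
#' safety levels follow `label_level_probs` (one canonical class per
#' level: no pediatric labeling for 0, adolescent for 1, child for 2,
#' infant/toddler for 3, full-term newborn for 4, preterm for 5).
#'
#' @param config a [synthetic_config()].
#' @param truth the `truth` component of [generate_cohort()] (fixes the
#'   drug index).
#' @return a [drug_label_table()]. Deterministic under the config seed.
#' @export
generate_labels <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, "labels"))
  classes <- c("no_pediatric_labeling", "adolescent", "child",
               "infant_toddler", "full_term_newborn", "preterm")
  drugs <- names(truth$drug_block)
  lv <- sample.int(6L, length(drugs), replace = TRUE,
                   prob = config$label_level_probs)
  drug_label_table(data.frame(drug_code = drugs,
                              statement = classes[lv],
                              stringsAsFactors = FALSE))
}

#' Evaluate recovery of the planted block structure
#'
#' Compares a recovered drug clustering with the planted blocks
#' (unassociated drugs count as their own planted block) via the adjusted
#' Rand index, plus per-block precision and recall of the best-matching
#' recovered cluster.
#'
#' @param clustering a [cluster_drugs()] result.
#' @param truth the `truth` component of [generate_cohort()].
#' @return list with `ari` and `per_block`, a data.frame of
#'   `block`, `best_cluster`, `precision`, `recall`.
#' @export
evaluate_recovery <- function(clustering, truth) {
  part <- clustering$partition
  planted <- truth$drug_block[names(part)]
  ari <- mclust::adjustedRandIndex(part, planted)
  per_block <- do.call(rbind, lapply(sort(unique(planted)), function(b) {
    members <- names(planted)[planted == b]
    hits <- table(part[members])
    best <- as.integer(names(hits)[which.max(hits)])
    in_best <- sum(part[members] == best)
    data.frame(block = b, best_cluster = best,
               precision = in_best / sum(part == best),
               recall = in_best / length(members))
  }))
  list(ari = ari, per_block = per_block)
}
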