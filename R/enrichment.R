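#' Build encounter-level drug-diagnosis pair counts
#'
#' Every drug code and diagnosis code recorded under the same inpatient
#' encounter forms one drug-diagnosis association pair; an encounter with
#' `|D|` distinct drugs and `|G|` distinct diagnoses contributes
#' `|D| x |G|` pairs. The hypergeometric universe is the multiset of these
#' pairs over all encounters: `N` is the total pair count, `K[d]` the
#' pairs involving drug `d`, `n[g]` the pairs involving diagnosis `g`, and
#' `k[d,g]` the number of encounters in which `d` and `g` co-occur.
#' Margins satisfy `sum(K) == sum(n) == sum(k) == N`.
#'
#' @param encounters an [encounter_table()].
#' @return object of class `pair_counts`: list with `N`, named vectors `K`
#'   and `n`, a data.frame `pairs` (`drug_code`, `diagnosis_code`, `k`),
#'   and the full `drugs` / `diagnoses` vocabularies of the cohort
#'   (including codes that never co-occur).
#' @export
build_pairs <- function(encounters) {
  stopifnot(inherits(encounters, "encounter_table"))
  de <- encounters$drug_events
  ge <- encounters$diagnosis_events
  drugs <- sort(unique(de$drug_code))
  diagnoses <- sort(unique(ge$diagnosis_code))
  if (nrow(de) == 0L || nrow(ge) == 0L) {
    stop("empty universe: no encounter has both a drug and a diagnosis")
  }

  n_dx_per_enc <- table(ge$encounter_id)
  n_drug_per_enc <- table(de$encounter_id)

  # pairs only form in encounters with both sides
  both <- intersect(names(n_dx_per_enc), names(n_drug_per_enc))
  if (length(both) == 0L) {
    stop("empty universe: no encounter has both a drug and a diagnosis")
  }

  # margins: drug contributes |G_e| pairs per encounter it appears in
  de_b <- de[de$encounter_id %in% both, , drop = FALSE]
  ge_b <- ge[ge$encounter_id %in% both, , drop = FALSE]
  K <- tapply(as.numeric(n_dx_per_enc[de_b$encounter_id]), de_b$drug_code, sum)
  n <- tapply(as.numeric(n_drug_per_enc[ge_b$encounter_id]),
              ge_b$diagnosis_code, sum)
  K_full <- stats::setNames(numeric(length(drugs)), drugs)
  K_full[names(K)] <- K
  n_full <- stats::setNames(numeric(length(diagnoses)), diagnoses)
  n_full[names(n)] <- n

  pairs <- merge(de_b, ge_b, by = "encounter_id")
  cooc <- stats::aggregate(list(k = rep(1L, nrow(pairs))),
                           pairs[, c("drug_code", "diagnosis_code")], sum)
  N <- sum(cooc$k)

  structure(list(N = N, K = K_full, n = n_full, pairs = cooc,
                 drugs = drugs, diagnoses = diagnoses,
                 n_encounters = length(encounters$encounters)),
            class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  cat("pair_counts:", x$N, "drug-diagnosis association pairs over",
      length(x$drugs), "drugs x", length(x$diagnoses), "diagnoses;",
      nrow(x$pairs), "distinct co-occurring pairs\n")
  invisible(x)
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X` hypergeometric with population size `N`, `K`
#' success states and `n` draws — the probability that a drug appearing in
#' `K` of the `N` association pairs shares at least `k` pairs with a
#' diagnosis appearing in `n` of them, under random pairing. Computed via
#' the survival function at `k - 1` so large observed counts do not suffer
#' cancellation.
#'
#' @param k observed co-occurrence count.
#' @param K pairs involving the drug.
#' @param n pairs involving the diagnosis.
#' @param N total pairs.
#' @return probability in (0, 1]; vectorised over its arguments.
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  bad <- k < 0 | k > pmin(K, n) | K > N | n > N | K < 0 | n < 0
  if (any(bad)) {
    stop("hypergeometric bounds violated: need 0 <= k <= min(K, n), K <= N, n <= N")
  }
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Hypergeometric enrichment with Bonferroni control
#'
#' Tests every drug-diagnosis pair observed to co-occur at least once
#' (`k >= 1`) for over-representation with the one-sided upper-tail
#' hypergeometric test, then applies Bonferroni correction over the tested
#' family: `p_adj = min(1, m * p_raw)` with `m` the family size.
#' Associations with `p_adj < alpha` are flagged significant.
#'
#' @param pairs a [build_pairs()] result.
#' @param alpha family-wise significance threshold (default 0.05).
#' @param family `"nonzero"` (default): `m` = number of pairs with
#'   `k >= 1`; `"all"`: `m` = number of drugs times number of diagnoses.
#' @return `association_table` data.frame with columns `drug_code`,
#'   `diagnosis_code`, `k`, `K`, `n`, `N`, `p_raw`, `p_adj`,
#'   `significant`; attributes `m`, `alpha`, `drugs`, `diagnoses`.
#' @export
enrich <- function(pairs, alpha = 0.05, family = c("nonzero", "all")) {
  stopifnot(inherits(pairs, "pair_counts"), alpha > 0, alpha < 1)
  family <- match.arg(family)
  tab <- pairs$pairs
  tab$K <- as.numeric(pairs$K[tab$drug_code])
  tab$n <- as.numeric(pairs$n[tab$diagnosis_code])
  tab$N <- pairs$N
  tab$p_raw <- hypergeom_pvalue(tab$k, tab$K, tab$n, tab$N)
  m <- if (family == "nonzero") nrow(tab) else
    length(pairs$drugs) * length(pairs$diagnoses)
  tab$p_adj <- pmin(1, m * tab$p_raw)
  tab$significant <- tab$p_adj < alpha
  tab <- tab[order(tab$p_adj, tab$drug_code, tab$diagnosis_code), ]
  rownames(tab) <- NULL
  tab <- tab[, c("drug_code", "diagnosis_code", "k", "K", "n", "N",
                 "p_raw", "p_adj", "significant")]
  attr(tab, "m") <- m
  attr(tab, "alpha") <- alpha
  attr(tab, "drugs") <- pairs$drugs
  attr(tab, "diagnoses") <- pairs$diagnoses
  class(tab) <- c("association_table", "data.frame")
  tab
}

#' Binary significant-association matrix
#'
#' Converts an association table to the drugs x diagnoses 0/1 matrix whose
#' entry is 1 exactly at the Bonferroni-significant pairs. The matrix
#' spans every drug and diagnosis present in the cohort, so a drug with no
#' significant diagnosis keeps an all-zero row — these drugs later collapse
#' into a single no-association cluster.
#'
#' @param assoc an [enrich()] result.
#' @param drugs,diagnoses optional explicit row/column vocabularies;
#'   default to the cohort vocabularies carried by `assoc`.
#' @return integer 0/1 matrix with drug codes as rownames and diagnosis
#'   codes as colnames.
#' @export
significance_matrix <- function(assoc, drugs = NULL, diagnoses = NULL) {
  stopifnot(inherits(assoc, "association_table") || is.data.frame(assoc))
  if (is.null(drugs)) drugs <- attr(assoc, "drugs")
  if (is.null(diagnoses)) diagnoses <- attr(assoc, "diagnoses")
  if (is.null(drugs)) drugs <- sort(unique(assoc$drug_code))
  if (is.null(diagnoses)) diagnoses <- sort(unique(assoc$diagnosis_code))
  m <- matrix(0L, length(drugs), length(diagnoses),
              dimnames = list(drugs, diagnoses))
  sig <- assoc[assoc$significant, , drop = FALSE]
  if (nrow(sig) > 0) {
    m[cbind(match(sig$drug_code, drugs),
            match(sig$diagnosis_code, diagnoses))] <- 1L
  }
  m
}
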