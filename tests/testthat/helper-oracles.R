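# Independent oracles and tiny fixture builders used across the suite.

# Brute-force upper-tail hypergeometric probability by direct pmf
# summation: P(X >= k) = sum_{i >= k} C(K,i) C(N-K, n-i) / C(N,n).
# Deliberately built from choose(), not phyper().
hyper_tail_bruteforce <- function(k, K, n, N) {
  i <- seq(max(k, 0), min(K, n))
  if (length(i) == 0L || k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Nested-loop Jaccard distance matrix recomputation from a binary matrix.
jaccard_bruteforce <- function(binmat) {
  n <- nrow(binmat)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      si <- colnames(binmat)[binmat[i, ] == 1]
      sj <- colnames(binmat)[binmat[j, ] == 1]
      u <- length(union(si, sj))
      d[i, j] <- if (u == 0) 0 else 1 - length(intersect(si, sj)) / u
    }
  }
  dimnames(d) <- list(rownames(binmat), rownames(binmat))
  d
}

# Minimal encounter table from compact per-encounter drug/diagnosis lists.
make_encounters <- function(drug_list, dx_list) {
  enc_ids <- union(names(drug_list), names(dx_list))
  de <- do.call(rbind, lapply(names(drug_list), function(e)
    if (length(drug_list[[e]]) > 0)
      data.frame(encounter_id = e, drug_code = drug_list[[e]])))
  ge <- do.call(rbind, lapply(names(dx_list), function(e)
    if (length(dx_list[[e]]) > 0)
      data.frame(encounter_id = e, diagnosis_code = dx_list[[e]])))
  encounter_table(de, ge, encounter_ids = enc_ids)
}

# Random 0/1 matrix with named rows/cols.
random_binmat <- function(n_drugs, n_dx, p = 0.3) {
  m <- matrix(rbinom(n_drugs * n_dx, 1L, p), n_drugs, n_dx,
              dimnames = list(paste0("d", seq_len(n_drugs)),
                              paste0("g", seq_len(n_dx))))
  m
}

read_tsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, ...)
}
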