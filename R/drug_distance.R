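#' Jaccard drug-drug distance matrix
#'
#' Pairwise Jaccard distances between the significant-diagnosis sets of
#' all drugs: `d(i, j) = 1 - |d_i intersect d_j| / |d_i union d_j|`, where
#' `d_i` is row `i` of the binary significant-association matrix read as a
#' set of diagnoses. Two drugs with empty sets get distance 0 (see
#' [jaccard_distance()]), so drugs with no significant association are
#' mutually indistinguishable and maximally distant from all others.
#'
#' The result is a metric: symmetric, zero diagonal, values in \[0, 1\],
#' and the triangle inequality holds.
#'
#' @param binmat drugs x diagnoses 0/1 matrix (e.g. from
#'   [significance_matrix()]).
#' @return symmetric numeric matrix of Jaccard distances with the drug
#'   codes of `binmat` as dimnames.
#' @export
distance_matrix <- function(binmat) {
  stopifnot(is.matrix(binmat))
  if (nrow(binmat) < 2L) stop("need at least 2 drugs to build distances")
  if (!all(binmat %in% c(0, 1))) stop("binmat entries must be 0/1")
  storage.mode(binmat) <- "numeric"
  inter <- tcrossprod(binmat)
  sizes <- rowSums(binmat)
  un <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / un
  d[un == 0] <- 0        # empty-vs-empty convention
  diag(d) <- 0
  dimnames(d) <- list(rownames(binmat), rownames(binmat))
  d
}
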