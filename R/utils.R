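#' @keywords internal
"_PACKAGE"

# Stable per-stage seed derivation: one pipeline seed deterministically
# yields distinct sub-seeds for k-means initialisation, bootstrap
# resampling, cohort generation etc. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# trim whitespace, drop empties; used on every code column
normalize_codes <- function(x) {
  x <- trimws(as.character(x))
  x
}

#' Jaccard distance between two sets
#'
#' One minus the ratio of intersection size to union size. Two empty sets
#' have distance 0 (they are indistinguishable); an empty set versus a
#' nonempty set has distance 1. This convention makes drugs with no
#' significant diagnosis mutually close and maximally far from all
#' associated drugs, so they collect into a single cluster downstream.
#'
#' @param set_i,set_j character vectors interpreted as sets (duplicates
#'   ignored).
#' @return numeric distance in \[0, 1\].
#' @examples
#' jaccard_distance(c("a", "b", "c"), c("b", "c", "d")) # 0.5
#' @export
jaccard_distance <- function(set_i, set_j) {
  set_i <- unique(set_i)
  set_j <- unique(set_j)
  u <- length(union(set_i, set_j))
  if (u == 0L) return(0)
  1 - length(intersect(set_i, set_j)) / u
}

# Jaccard similarity between two membership index vectors (for bootstrap
# cluster stability).
jaccard_overlap <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}
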