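#' Compare two partitions of the same samples (ARI and VII)
#'
#' Computes the Adjusted Rand Index (chance-corrected pair agreement, 1 iff
#' the partitions are identical up to relabelling) and the Variation of
#' Information (an information-theoretic metric on partitions, 0 iff
#' identical up to relabelling), reported in bits.
#'
#' @param a,b Cluster label vectors over the same samples (any atomic type;
#'   labels are compared within, never across, the two vectors).
#' @return Tibble with `ari`, `vii` and `vii_unit = "bits"`.
#' @export
compare_partitions <- function(a, b) {
  if (length(a) != length(b)) abort("partitions must cover the same samples")
  if (length(a) < 2L) abort("need >= 2 samples to compare partitions")
  tibble(ari = ari_index(a, b), vii = vi_index(a, b), vii_unit = "bits")
}

# Adjusted Rand Index from the contingency table with the usual
# expected-index correction
ari_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

# Variation of Information H(a) + H(b) - 2 I(a;b), in bits
vi_index <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab)
  pb <- colSums(tab)
  h <- function(p) -sum(p[p > 0] * log2(p[p > 0]))
  mi <- sum(tab[tab > 0] * log2(tab[tab > 0] /
                                  outer(pa, pb)[tab > 0]))
  max(0, h(pa) + h(pb) - 2 * mi)
}
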