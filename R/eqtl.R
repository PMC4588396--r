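#' Correlate local copy number with transcript expression (cis-eQTL scan)
#'
#' For every gene with both a CN state and an expression row, computes the
#' Pearson correlation between its integer CN state and its own log2
#' expression across the shared samples — the self-locus dosage effect,
#' which lies within any cis window (< 1 Mb) by construction. Two-sided
#' p-values come from the t transform of r. Genes whose CN state does not
#' vary are excluded and reported via the `excluded` attribute.
#'
#' @param cn_matrix Integer gene x sample CN matrix.
#' @param expr_matrix Gene-level log2 expression matrix.
#' @param samples Optional sample ids to use (default: the intersection of
#'   the two matrices' columns, typically the tumour samples).
#' @return Tibble with `gene_id`, `r`, `p_value`, `n_samples`, ordered as
#'   the input annotation; attribute `excluded` lists no-variance genes.
#' @export
cis_correlations <- function(cn_matrix, expr_matrix, samples = NULL) {
  stopifnot_matrix(cn_matrix, "cn_matrix")
  stopifnot_matrix(expr_matrix, "expr_matrix")
  samples <- samples %||% intersect(colnames(cn_matrix), colnames(expr_matrix))
  if (length(samples) < 3L) abort("need >= 3 shared samples")
  genes <- intersect(rownames(cn_matrix), rownames(expr_matrix))
  if (!length(genes)) abort("no genes shared between CN and expression")

  cn <- cn_matrix[genes, samples, drop = FALSE]
  ex <- expr_matrix[genes, samples, drop = FALSE]
  n <- length(samples)

  cn_c <- cn - rowMeans(cn)
  ex_c <- ex - rowMeans(ex)
  cn_ss <- rowSums(cn_c^2)
  ex_ss <- rowSums(ex_c^2)
  varies <- cn_ss > 0 & ex_ss > 0

  r <- rowSums(cn_c * ex_c)[varies] / sqrt(cn_ss[varies] * ex_ss[varies])
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0

  out <- tibble(
    gene_id = genes[varies], r = unname(r), p_value = unname(p), n_samples = n
  )
  attr(out, "excluded") <- tibble(
    gene_id = genes[!varies],
    reason = ifelse(cn_ss[!varies] == 0, "no CN variance", "no expression variance")
  )
  out
}

#' Select the strongest dosage-coupled features
#'
#' Ranks genes by absolute correlation (ties by smaller p-value, then gene
#' id) and returns the top `n`. Ranking by magnitude rather than a
#' significance cutoff matches selecting a fixed feature count.
#'
#' @param features Tibble from [cis_correlations()].
#' @param n Number of genes to select.
#' @return Character vector of `n` gene ids.
#' @export
select_features <- function(features, n) {
  if (n > nrow(features)) abort("n exceeds the number of scored features")
  features |>
    arrange(desc(abs(.data$r)), .data$p_value, .data$gene_id) |>
    dplyr::slice(seq_len(n)) |>
    pull("gene_id")
}
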