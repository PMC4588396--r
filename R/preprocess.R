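#' Quantile-normalize a log2 expression matrix
#'
#' Forces every sample (column) onto the common reference distribution given
#' by the row-wise mean of the sorted columns, preserving within-column
#' ranks. Ties receive the mean of the reference values spanning their rank
#' range.
#'
#' @param values Numeric feature x sample matrix.
#' @return Matrix of the same shape.
#' @export
quantile_normalize <- function(values) {
  stopifnot_matrix(values, "values")
  if (ncol(values) < 2L) abort("quantile normalization needs >= 2 samples")
  if (any(!is.finite(values))) abort("expression matrix contains non-finite values")
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Collapse probes to one row per gene by maximum IQR
#'
#' Only probes flagged `perfect` are eligible; each gene is represented by
#' its most variable (highest interquartile range) perfect probe. IQR ties
#' break to the lexicographically smallest `feature_id`. Genes with no
#' perfect probe are dropped and reported via the `dropped_genes` attribute.
#'
#' @param expression List with `values` (probe x sample) and `features`
#'   (tibble with `feature_id`, `gene_id`, `quality_flag`).
#' @return Gene x sample matrix (rownames are gene ids) with attributes
#'   `probe_map` (tibble gene_id/feature_id) and `dropped_genes`.
#' @export
collapse_probes <- function(expression) {
  values <- expression$values
  feat <- expression$features
  stopifnot_matrix(values, "expression$values")
  eligible <- feat$quality_flag == "perfect" & !is.na(feat$gene_id)
  all_genes <- unique(feat$gene_id[!is.na(feat$gene_id)])

  iqr <- row_iqr(values)
  chosen <- feat[eligible, ] |>
    mutate(iqr = iqr[.data$feature_id]) |>
    arrange(.data$gene_id, desc(.data$iqr), .data$feature_id) |>
    group_by(.data$gene_id) |>
    dplyr::slice(1L) |>
    ungroup()

  dropped <- setdiff(all_genes, chosen$gene_id)
  if (length(dropped)) {
    inform(sprintf("collapse_probes: dropped %d gene(s) with no perfect probe: %s",
                   length(dropped), paste(head(dropped, 10), collapse = ", ")))
  }
  out <- values[chosen$feature_id, , drop = FALSE]
  rownames(out) <- chosen$gene_id
  attr(out, "probe_map") <- chosen |> select("gene_id", "feature_id")
  attr(out, "dropped_genes") <- dropped
  out
}

#' Remove batch effects with parametric empirical-Bayes adjustment
#'
#' Location/scale batch correction: features are standardized, per-batch
#' additive and multiplicative effects are estimated and shrunk towards
#' batch-level priors (normal for location, inverse-gamma for scale), then
#' removed and the grand structure restored. The adjustment preserves matrix
#' dimensions and per-feature grand means.
#'
#' @param values Feature x sample matrix.
#' @param batch Batch label per sample (recycled names must match columns).
#' @param covariates Optional model matrix of biological covariates to
#'   protect (e.g. tissue type); `NULL` adjusts with an intercept-only model.
#' @param allow_single_batch If `TRUE`, a single-batch input is returned
#'   unchanged instead of erroring.
#' @return Adjusted matrix, same shape.
#' @export
combat_adjust <- function(values, batch, covariates = NULL,
                          allow_single_batch = FALSE) {
  stopifnot_matrix(values, "values")
  batch <- as.character(batch)
  if (length(batch) != ncol(values)) {
    abort("`batch` must have one label per sample column")
  }
  if (length(unique(batch)) < 2L) {
    if (allow_single_batch) return(values)
    abort("need >= 2 batches (or set allow_single_batch = TRUE)")
  }
  if (any(table(batch) < 2L)) abort("each batch needs >= 2 samples")
  if (!is.null(covariates)) {
    full <- cbind(stats::model.matrix(~batch), covariates)
    if (qr(full)$rank < ncol(full)) {
      abort("batch is confounded with a modelled covariate")
    }
  }
  out <- sva::ComBat(dat = values, batch = batch, mod = covariates,
                     par.prior = TRUE, prior.plots = FALSE)
  # the EB location/scale adjustment moves feature means slightly under
  # unbalanced batches; restore each feature's grand mean exactly
  out <- out - rowMeans(out) + rowMeans(values)
  dimnames(out) <- dimnames(values)
  out
}

#' Rank features by interquartile range and keep the most variable
#'
#' @param values Feature x sample matrix.
#' @param n Number of features to keep.
#' @return Character vector of the `n` feature ids sorted by IQR descending;
#'   ties break by feature id.
#' @export
top_variable_features <- function(values, n = 100L) {
  stopifnot_matrix(values, "values")
  if (n > nrow(values)) abort("n exceeds the number of features")
  iqr <- row_iqr(values)
  ord <- order(-iqr, rownames(values))
  rownames(values)[ord][seq_len(n)]
}

#' Filter samples by tumour-cell content
#'
#' Tumour samples below the cellularity threshold are excluded (the boundary
#' is inclusive: a sample at exactly the threshold is kept); benign and
#' germline samples are retained regardless of cellularity.
#'
#' @param clinical Clinical tibble (see [read_clinical()]).
#' @param min_cellularity Threshold in percent (20 for a discovery-style
#'   cohort, 70 for a strict validation cohort).
#' @return Character vector of retained sample ids.
#' @export
filter_samples <- function(clinical, min_cellularity = 20) {
  keep <- clinical$tissue != "tumour" |
    (!is.na(clinical$cellularity_pct) &
       clinical$cellularity_pct >= min_cellularity)
  clinical$sample[keep]
}
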