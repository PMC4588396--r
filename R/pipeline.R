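#' Discovery-cohort pipeline configuration
#'
#' @param min_cellularity Minimum tumour content (%) for inclusion.
#' @param n_top_features Feature count for the integrative fit when no grid
#'   search is requested.
#' @param K Cluster count when no grid search is requested.
#' @param lambda Lasso penalty for the integrative fit.
#' @param combat Adjust batch effects when more than one batch is present.
#' @param min_recurrence Minimum altered-cohort fraction for a gene's CN
#'   state to count as recurrent.
#' @param max_rank_genes,max_rank_pga Confidence-rank cutoffs for gene-state
#'   mapping and percent genome altered.
#' @param grid Optional list with `K_range`, `n_features_grid`,
#'   `lambda_grid`, `n_restarts` to run [select_model()] instead of a single
#'   fit.
#' @param seed Root seed; every stochastic stage derives a named stream.
#' @return A `run_config` list.
#' @export
run_config <- function(min_cellularity = 20, n_top_features = 100L,
                       K = 5L, lambda = 0.03, combat = TRUE,
                       min_recurrence = 0.10, max_rank_genes = 2L,
                       max_rank_pga = 1L, grid = NULL, seed = 1L) {
  structure(
    list(min_cellularity = min_cellularity, n_top_features = n_top_features,
         K = K, lambda = lambda, combat = combat,
         min_recurrence = min_recurrence, max_rank_genes = max_rank_genes,
         max_rank_pga = max_rank_pga, grid = grid, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the discovery analysis end to end
#'
#' Stages: cellularity filter -> quantile normalization -> probe collapse ->
#' batch adjustment -> segment-to-gene CN states -> cis-eQTL feature
#' selection -> integrative latent-variable fit (optionally with model
#' selection) -> centroid training -> per-subtype differential expression
#' vs benign -> survival analyses -> percent genome altered by cluster.
#' Every stage appends a manifest row (stage, parameters, counts).
#'
#' @param segments,expression,clinical,annotation Cohort inputs in the
#'   formats produced by the readers in this package (or by
#'   [generate_cohort()]).
#' @param config A [run_config()].
#' @return List of class `discovery_run`: `model`, `centroids`,
#'   `eqtl`, `selected_genes`, `de`, `survival` (logrank + KM table),
#'   `pga`, `manifest`, plus the processed matrices.
#' @export
run_discovery <- function(segments, expression, clinical, annotation,
                          config = run_config()) {
  manifest <- list()
  log_stage <- function(stage, ...) {
    pars <- list(...)
    manifest[[length(manifest) + 1L]] <<- tibble(
      stage = stage,
      detail = paste(names(pars), unlist(pars), sep = "=", collapse = "; ")
    )
    inform(sprintf("[%s] %s", stage, manifest[[length(manifest)]]$detail))
  }
  if (is.null(segments)) abort("cnv stage: no copy-number segment input")

  keep <- filter_samples(clinical, config$min_cellularity)
  keep <- intersect(keep, colnames(expression$values))
  log_stage("filter_samples", min_cellularity = config$min_cellularity,
            kept = length(keep))

  values <- expression$values[, keep, drop = FALSE]
  values <- quantile_normalize(values)
  log_stage("quantile_normalize", features = nrow(values), samples = ncol(values))

  expr_gene <- collapse_probes(list(values = values,
                                    features = expression$features))
  log_stage("collapse_probes", genes = nrow(expr_gene),
            dropped = length(attr(expr_gene, "dropped_genes")))

  batches <- clinical$batch[match(colnames(expr_gene), clinical$sample)]
  if (config$combat && length(unique(batches)) > 1L) {
    expr_gene <- combat_adjust(expr_gene, batches)
    log_stage("combat_adjust", batches = length(unique(batches)))
  }

  tumour <- clinical$sample[clinical$tissue == "tumour"]
  tumour <- intersect(tumour, colnames(expr_gene))
  cn <- segments_to_gene_states(segments, annotation, samples = tumour,
                                max_rank = config$max_rank_genes)
  rec <- cn_recurrence(cn)
  recurrent <- filter_recurrent(rec, config$min_recurrence)
  log_stage("cnv", genes = nrow(cn), recurrent = length(recurrent),
            max_rank = config$max_rank_genes)

  feats <- cis_correlations(cn[recurrent, , drop = FALSE], expr_gene,
                            samples = tumour)
  n_sel <- min(config$n_top_features, nrow(feats))
  selected <- select_features(feats, n_sel)
  log_stage("eqtl", scored = nrow(feats), selected = n_sel)

  blocks <- list(
    expr = expr_gene[selected, tumour, drop = FALSE],
    cn = cn[selected, tumour, drop = FALSE] * 1.0
  )
  if (!is.null(config$grid)) {
    g <- config$grid
    sel <- select_model(cn[recurrent, , drop = FALSE] * 1.0,
                        expr_gene, feats,
                        K_range = g$K_range %||% 2:11,
                        n_features_grid = g$n_features_grid %||% n_sel,
                        lambda_grid = g$lambda_grid %||% config$lambda,
                        n_restarts = g$n_restarts %||% 5L,
                        seed = child_seed(config$seed, "grid"))
    model <- sel$model
    grid <- sel$grid
    selected <- select_features(feats, sel$chosen$n_features)
    blocks <- list(
      expr = expr_gene[selected, tumour, drop = FALSE],
      cn = cn[selected, tumour, drop = FALSE] * 1.0
    )
    log_stage("select_model", K = sel$chosen$K,
              n_features = sel$chosen$n_features, lambda = sel$chosen$lambda)
  } else {
    model <- fit_integrative_model(blocks, K = config$K,
                                   lambda = config$lambda,
                                   seed = child_seed(config$seed, "fit"))
    grid <- NULL
    log_stage("fit_integrative_model", K = config$K, lambda = config$lambda,
              variance_explained = round(model$variance_explained, 3))
  }

  centroids <- train_centroids(model, blocks)
  log_stage("train_centroids", K = centroids$K,
            features = length(centroids$feature_key))

  benign <- intersect(clinical$sample[clinical$tissue == "benign"],
                      colnames(expr_gene))
  de <- NULL
  if (length(benign) >= 2L && min(table(model$assignments)) >= 2L) {
    groups <- c(paste0("cluster", model$assignments[tumour]),
                rep("benign", length(benign)))
    de_fit <- fit_linear_de(expr_gene[, c(tumour, benign), drop = FALSE],
                            groups)
    de <- eb_shrink(de_fit)
    log_stage("diffexp", contrasts = length(unique(de$contrast)))
  }

  surv <- survival_table(clinical, assignments = model$assignments)
  survival_res <- NULL
  if (nrow(surv) && sum(surv$event) >= 1L &&
        length(unique(surv$cluster)) >= 2L) {
    survival_res <- list(
      logrank = logrank_test(surv, "cluster"),
      km = km_estimate(surv, "cluster")
    )
    log_stage("survival", logrank_p = signif(survival_res$logrank$p_value, 3))
  }

  pga_tab <- pga_all(segments, samples = tumour,
                     max_rank = config$max_rank_pga) |>
    mutate(cluster = unname(model$assignments[.data$sample]))
  pga_res <- list(
    per_sample = pga_tab,
    by_cluster = pga_by_group(pga_tab$pga, pga_tab$cluster)
  )
  log_stage("pga", kw_p = signif(pga_res$by_cluster$p_value, 3))

  structure(
    list(model = model, centroids = centroids, grid = grid,
         eqtl = feats, selected_genes = selected, de = de,
         survival = survival_res, pga = pga_res,
         expr_gene = expr_gene, cn = cn, blocks = blocks,
         manifest = list_rbind(manifest), config = config),
    class = "discovery_run"
  )
}

#' Transfer trained subtypes to a validation cohort
#'
#' Preprocesses the validation expression data the same way as discovery,
#' maps its CN segments to gene states, classifies samples by nearest
#' trained centroid, and evaluates prognosis (logrank across predicted
#' clusters). Optionally benchmarks signatures with the random-signature
#' null.
#'
#' @param centroids A [train_centroids()] object (or a `discovery_run`,
#'   whose centroids are used).
#' @param segments,expression,clinical,annotation Validation cohort inputs.
#' @param config A [run_config()] (use the validation cohort's cellularity
#'   threshold, e.g. 70).
#' @param signatures Optional named list of gene sets to score.
#' @param null_R Random signatures per benchmarked set (0 disables the
#'   null).
#' @return List of class `validation_run`: `assignments`, `survival`,
#'   `signatures`, `manifest`.
#' @export
run_validation <- function(centroids, segments, expression, clinical,
                           annotation, config = run_config(min_cellularity = 70),
                           signatures = NULL, null_R = 0L) {
  if (inherits(centroids, "discovery_run")) centroids <- centroids$centroids
  if (!ncol(expression$values)) abort("validation cohort is empty")

  keep <- filter_samples(clinical, config$min_cellularity)
  keep <- intersect(keep, colnames(expression$values))
  if (!length(keep)) abort("validation cohort is empty after filtering")
  values <- quantile_normalize(expression$values[, keep, drop = FALSE])
  expr_gene <- collapse_probes(list(values = values,
                                    features = expression$features))
  batches <- clinical$batch[match(colnames(expr_gene), clinical$sample)]
  if (config$combat && length(unique(batches)) > 1L) {
    expr_gene <- combat_adjust(expr_gene, batches)
  }
  tumour <- intersect(clinical$sample[clinical$tissue == "tumour"],
                      colnames(expr_gene))
  cn <- segments_to_gene_states(segments, annotation, samples = tumour,
                                max_rank = config$max_rank_genes)

  assignments <- classify_new_samples(centroids, list(
    expr = expr_gene[, tumour, drop = FALSE],
    cn = cn[, tumour, drop = FALSE] * 1.0
  ))

  asg <- setNames(assignments$cluster, assignments$sample)
  surv <- survival_table(clinical, assignments = asg)
  survival_res <- NULL
  if (nrow(surv) && sum(surv$event) >= 1L &&
        length(unique(surv$cluster)) >= 2L) {
    survival_res <- list(
      logrank = logrank_test(surv, "cluster"),
      km = km_estimate(surv, "cluster")
    )
  }

  sig_res <- NULL
  if (!is.null(signatures)) {
    sv <- survival_table(clinical)
    sig_res <- list(
      table = signature_comparison_table(signatures, expr_gene, sv,
                                         seed = child_seed(config$seed, "sig"))
    )
    if (null_R > 0L) {
      sig_res$null <- imap(signatures, function(genes, nm) {
        random_signature_null(genes, expr_gene, sv, R = null_R,
                              seed = child_seed(config$seed, paste0("null_", nm)))
      })
    }
  }

  structure(
    list(assignments = assignments, survival = survival_res,
         signatures = sig_res, expr_gene = expr_gene, cn = cn,
         config = config),
    class = "validation_run"
  )
}

#' Save trained subtype centroids as a portable plain-text archive
#'
#' The archive is a single TSV with `#`-prefixed metadata header lines, so
#' a validation run elsewhere can load a discovery-trained classifier.
#'
#' @param centroids A [train_centroids()] object.
#' @param path Output path.
#' @export
write_model <- function(centroids, path) {
  hdr <- c(
    sprintf("# integraPC subtype centroids"),
    sprintf("# K=%d", centroids$K),
    sprintf("# blocks=%s", paste(centroids$blocks, collapse = ","))
  )
  tab <- dplyr::bind_cols(
    tibble(feature_key = centroids$feature_key,
           center = unname(centroids$center),
           scale = unname(centroids$scale)),
    as_tibble(centroids$centroids)
  )
  writeLines(c(hdr, sub("\n$", "", readr::format_tsv(tab))), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- lines[startsWith(lines, "#")]
  K <- as.integer(sub("^# K=", "", hdr[grepl("^# K=", hdr)]))
  blocks <- strsplit(sub("^# blocks=", "", hdr[grepl("^# blocks=", hdr)]),
                     ",")[[1]]
  tab <- readr::read_tsv(I(lines[!startsWith(lines, "#")]),
                         col_types = readr::cols(feature_key = "c",
                                                 .default = "d"))
  centroids <- as.matrix(tab[, paste0("cluster", seq_len(K))])
  rownames(centroids) <- tab$feature_key
  structure(
    list(centroids = centroids,
         center = setNames(tab$center, tab$feature_key),
         scale = setNames(tab$scale, tab$feature_key),
         feature_key = tab$feature_key, blocks = blocks, K = K),
    class = "subtype_centroids"
  )
}
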