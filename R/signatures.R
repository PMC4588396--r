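#' Score a gene signature for prognostic power
#'
#' Standardizes the signature genes' expression rows, partitions the
#' samples into two groups by k-means in signature space (>= 50 restarts,
#' seeded), and tests the two groups with a logrank test on
#' time-to-relapse. Deterministic for a fixed seed.
#'
#' @param genes Character vector of gene ids (duplicates are dropped with a
#'   note).
#' @param expr_matrix Gene x sample log2 matrix.
#' @param surv Survival tibble with `sample`, `time`, `event`.
#' @param seed Seed for the k-means restarts.
#' @param nstart k-means restarts.
#' @return List of class `signature_score`: `genes` (matched), `n_matched`,
#'   `partition` (named 1/2 vector), `chi_square`, `p_value`; `percentile`
#'   and `null_summary` are `NULL` until [random_signature_null()] attaches
#'   them.
#' @export
score_signature <- function(genes, expr_matrix, surv, seed = 1L,
                            nstart = 50L) {
  stopifnot_matrix(expr_matrix, "expr_matrix")
  if (anyDuplicated(genes)) {
    inform(sprintf("score_signature: %d duplicate gene id(s) dropped",
                   sum(duplicated(genes))))
    genes <- unique(genes)
  }
  matched <- intersect(genes, rownames(expr_matrix))
  if (length(matched) < 3L) {
    abort(sprintf("fewer than 3 signature genes matched; missing: %s",
                  paste(setdiff(genes, matched), collapse = ", ")))
  }
  samples <- intersect(colnames(expr_matrix), surv$sample)
  if (length(samples) < 4L) abort("need >= 4 samples with survival data")

  Xs <- standardize_rows(expr_matrix[matched, samples, drop = FALSE])
  part <- withr::with_seed(child_seed(seed, "sig_kmeans"), {
    kmeans_assign(t(Xs), 2L, nstart)
  })
  names(part) <- samples

  sv <- surv[match(samples, surv$sample), ]
  sv$sig_group <- part
  lr <- logrank_test(sv, "sig_group")

  structure(
    list(genes = matched, n_matched = length(matched), partition = part,
         chi_square = lr$chi_square, p_value = lr$p_value,
         percentile = NULL, null_summary = NULL),
    class = "signature_score"
  )
}

#' Benchmark a signature against random gene sets of the same size
#'
#' Draws `R` random signatures of `m` genes (without replacement, from all
#' assayed genes), scores each with [score_signature()], and reports the
#' target's percentile: `100 * (# null chi-squares <= target) / R`. Larger
#' logrank chi-square means better separation of relapse groups.
#'
#' @param target_genes Gene ids of the signature under test.
#' @param expr_matrix,surv,seed As in [score_signature()].
#' @param R Number of random signatures.
#' @param m Random signature size (default: the number of matched target
#'   genes).
#' @param exclude_target If `TRUE`, target genes are excluded from the null
#'   draws; default draws from all genes.
#' @return The target's `signature_score` with `percentile`, `n_better`
#'   (null draws strictly better) and `null_summary` (R, mean, sd) filled
#'   in; the null chi-squares are in attribute `null_chisq`.
#' @export
random_signature_null <- function(target_genes, expr_matrix, surv,
                                  R = 1000L, m = NULL, seed = 1L,
                                  exclude_target = FALSE) {
  if (R < 1L) abort("R must be >= 1")
  target <- score_signature(target_genes, expr_matrix, surv, seed = seed)
  m <- m %||% target$n_matched
  pool <- rownames(expr_matrix)
  if (exclude_target) pool <- setdiff(pool, target$genes)
  if (m > length(pool)) abort("m exceeds the number of assayed genes")

  null_chisq <- withr::with_seed(child_seed(seed, "null_draws"), {
    draw_seeds <- sample.int(2^30, R)
    vapply(seq_len(R), function(i) {
      gs <- sample(pool, m)
      score_signature(gs, expr_matrix, surv, seed = draw_seeds[i])$chi_square
    }, numeric(1))
  })

  target$percentile <- 100 * sum(null_chisq <= target$chi_square) / R
  target$n_better <- sum(null_chisq > target$chi_square)
  target$null_summary <- tibble(R = R, mean = mean(null_chisq),
                                sd = sd(null_chisq))
  attr(target, "null_chisq") <- null_chisq
  target
}

#' Refine a ~50-gene subset that best defines one subtype
#'
#' Ranks genes by a one-vs-rest discriminative score: the absolute
#' standardized mean difference between the cluster and all other samples,
#' computed on both the expression and the CN component of each gene; a
#' gene's score is the larger of its two components, and the top
#' `target_size` genes form the subset.
#'
#' @param model Fitted [fit_integrative_model()] object.
#' @param cluster Cluster index to characterise.
#' @param blocks Named list of the (unstandardized) feature x sample blocks
#'   used in training; rownames are gene ids.
#' @param target_size Number of genes to return (default 50).
#' @return Character vector of gene ids, best-discriminating first; scores
#'   in attribute `scores`.
#' @export
refine_cluster_signature <- function(model, cluster, blocks,
                                     target_size = 50L) {
  asg <- model$assignments
  if (!cluster %in% asg) abort(sprintf("cluster %s has no samples", cluster))
  in_cl <- names(asg)[asg == cluster]
  out_cl <- names(asg)[asg != cluster]

  score_block <- function(b) {
    Xs <- standardize_rows(b[, names(asg), drop = FALSE])
    d <- rowMeans(Xs[, in_cl, drop = FALSE]) -
      rowMeans(Xs[, out_cl, drop = FALSE])
    abs(d)
  }
  per_block <- lapply(blocks, score_block)
  genes <- unique(unlist(lapply(blocks, rownames)))
  scores <- vapply(genes, function(g) {
    max(vapply(per_block, function(s) if (g %in% names(s)) s[[g]] else 0,
               numeric(1)))
  }, numeric(1))
  if (max(scores) < 0.2) {
    warn("near-zero discriminative scores: cluster is not distinguishable")
  }
  ord <- order(-scores, genes)
  top <- genes[ord][seq_len(min(target_size, length(genes)))]
  attr(top, "scores") <- scores[ord]
  top
}

#' Score a named collection of signatures on one cohort
#'
#' One row per signature: name, matched gene count, logrank chi-square and
#' p-value — the layout of a signature-benchmark table. Signatures that
#' fail to score (e.g. too few matched genes) get NA rows with a warning.
#'
#' @param signature_sets Named list of gene-id vectors (e.g. from
#'   [read_gmt()]).
#' @param expr_matrix,surv,seed As in [score_signature()].
#' @return Tibble with `signature`, `n_genes`, `chi_square`, `p_value`.
#' @export
signature_comparison_table <- function(signature_sets, expr_matrix, surv,
                                       seed = 1L) {
  if (!length(signature_sets)) {
    return(tibble(signature = character(), n_genes = integer(),
                  chi_square = numeric(), p_value = numeric()))
  }
  imap(signature_sets, function(genes, nm) {
    res <- tryCatch(
      score_signature(genes, expr_matrix, surv, seed = seed),
      error = function(e) {
        warn(sprintf("signature '%s' could not be scored: %s",
                     nm, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(res)) {
      tibble(signature = nm, n_genes = NA_integer_,
             chi_square = NA_real_, p_value = NA_real_)
    } else {
      tibble(signature = nm, n_genes = res$n_matched,
             chi_square = res$chi_square, p_value = res$p_value)
    }
  }) |> list_rbind()
}
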