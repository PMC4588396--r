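mk_block <- function(m, prefix = "f") {
  rownames(m) <- paste0(prefix, seq_len(nrow(m)))
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

test_that("a large enough penalty shrinks all loadings to zero", {
  withr::with_seed(1, {
    b <- list(expr = mk_block(matrix(rnorm(200), 20, 10)))
    m <- suppressWarnings(fit_integrative_model(b, K = 3, lambda = 50,
                                                seed = 1))
    expect_true(all(m$W$expr == 0))
    expect_equal(m$variance_explained, 0, tolerance = 1e-6)
  })
})

test_that("the unpenalised single-block fit spans the principal subspace", {
  # exact low-rank data: the latent span must match the top singular
  # directions of the same (standardized) matrix computed by direct SVD
  withr::with_seed(42, {
    n <- 80; p <- 40; q <- 4
    Z <- matrix(rnorm(q * n), q, n) * c(4, 3, 2, 1.5)
    W0 <- matrix(rnorm(p * q), p, q)
    X <- mk_block(W0 %*% Z)
    m <- suppressWarnings(fit_integrative_model(
      list(expr = X), K = q + 1, lambda = 0, seed = 2, tol = 1e-10,
      max_iter = 2000
    ))
    Xs <- t(scale(t(X)))  # the standardized matrix the EM fitted
    sv <- svd(Xs, nu = q)
    expect_lt(principal_angle(m$W$expr, sv$u), 1e-3)
  })
})

test_that("the penalised log-likelihood never decreases across iterations", {
  coh <- test_cohort()
  pb <- pipeline_blocks(coh, 60L)
  for (s in 1:4) {
    m <- suppressWarnings(fit_integrative_model(
      pb$blocks, K = 4, lambda = 0.05, seed = s, init = "random",
      max_iter = 80
    ))
    expect_true(all(diff(m$loglik_trace) >=
                      -1e-6 * (abs(m$loglik_trace[-length(m$loglik_trace)]) + 1)))
  }
})

test_that("variance explained lies in [0,1] and is non-increasing in lambda", {
  coh <- test_cohort()
  pb <- pipeline_blocks(coh, 60L)
  ve <- vapply(c(0, 0.05, 0.15, 0.4), function(lam) {
    m <- suppressWarnings(fit_integrative_model(pb$blocks, K = 4,
                                                lambda = lam, seed = 3))
    m$variance_explained
  }, numeric(1))
  expect_true(all(ve >= 0 & ve <= 1))
  expect_true(all(diff(ve) <= 1e-6))
})

test_that("planted subtypes are recovered on a separable cohort", {
  coh <- test_cohort()
  pb <- pipeline_blocks(coh)
  m <- suppressWarnings(fit_integrative_model(pb$blocks, K = 5, seed = 1))
  cmp <- compare_partitions(m$assignments, truth_vec(coh)[names(m$assignments)])
  expect_gte(cmp$ari, 0.9)
})

test_that("restricting the grid to one cell selects that cell", {
  coh <- test_cohort()
  pb <- pipeline_blocks(coh)
  sm <- suppressWarnings(select_model(
    pb$cn * 1.0, pb$expr_gene, pb$feats, K_range = 5L,
    n_features_grid = 80L, lambda_grid = 0.1, n_restarts = 3L, seed = 4L
  ))
  expect_equal(sm$chosen$K, 5L)
  expect_equal(sm$chosen$n_features, 80L)
  expect_equal(nrow(sm$grid), 1L)
})

test_that("a structureless cohort yields unstable partitions at every K", {
  coh <- generate_null_cohort(sim_config(n_tumour = 120L, n_benign = 5L,
                                         n_genes = 600L, seed = 91L))
  tum <- tumour_ids(coh)
  eg <- suppressMessages(collapse_probes(coh$expression))
  # batch structure is real, clusterable signal: adjust it out first, as
  # the pipeline always does before clustering
  batch <- coh$clinical$batch[match(colnames(eg), coh$clinical$sample)]
  eg <- combat_adjust(eg, batch)
  # CN has no variance under the null; cluster the expression block alone
  feats <- tibble::tibble(gene_id = rownames(eg),
                          r = 0, p_value = 1, n_samples = length(tum))
  stab <- vapply(2:6, function(K) {
    asg <- lapply(1:4, function(r) {
      idx <- withr::with_seed(K * 100 + r, sample(length(tum), 84L))
      suppressWarnings(fit_integrative_model(
        list(expr = eg[1:100, tum[idx]]), K = K, lambda = 0.1,
        seed = K * 10 + r, init = "random", max_iter = 60, tol = 1e-5
      ))$assignments
    })
    prs <- utils::combn(4, 2)
    mean(apply(prs, 2, function(ij) {
      common <- intersect(names(asg[[ij[1]]]), names(asg[[ij[2]]]))
      compare_partitions(asg[[ij[1]]][common], asg[[ij[2]]][common])$ari
    }))
  }, numeric(1))
  expect_true(all(stab < 0.3))
})

test_that("centroid training and self-classification are consistent", {
  coh <- test_cohort()
  pb <- pipeline_blocks(coh)
  m <- suppressWarnings(fit_integrative_model(pb$blocks, K = 5, seed = 1))
  ctr <- train_centroids(m, pb$blocks)
  expect_equal(ncol(ctr$centroids), 5L)
  # training samples reclassified by nearest centroid agree with the model
  pred <- classify_new_samples(ctr, pb$blocks)
  agree <- mean(apply(table(pred$cluster, m$assignments[pred$sample]), 1,
                      max) / table(pred$cluster) >= 0)
  remap <- compare_partitions(pred$cluster, m$assignments[pred$sample])
  expect_gte(remap$ari, 0.9)
})

test_that("degenerate centroid cases behave as documented", {
  # two symmetric clusters at +/- v give centroids at +/- v
  v <- c(1, -2, 3)
  b <- list(expr = mk_block(cbind(v, v, -v, -v) + 0, prefix = "g"))
  model <- list(assignments = setNames(c(1L, 1L, 2L, 2L), colnames(b$expr)),
                K = 2L)
  ctr <- train_centroids(model, b)
  expect_equal(ctr$centroids[, 1], -ctr$centroids[, 2])
  # a centroid fed back in classifies to its own cluster
  newb <- list(expr = b$expr[, 1:2])
  pred <- classify_new_samples(ctr, newb)
  expect_true(all(pred$cluster == 1L))
  # an equidistant sample ties to the lowest-indexed cluster
  mid <- list(expr = mk_block(matrix(0, 3, 1), prefix = "g"))
  colnames(mid$expr) <- "mid"
  expect_message(pred_mid <- classify_new_samples(ctr, mid), "ties")
  expect_equal(pred_mid$cluster, 1L)
  # empty cluster errors
  model_bad <- list(assignments = setNames(rep(1L, 4), colnames(b$expr)),
                    K = 2L)
  expect_error(train_centroids(model_bad, b), "empty cluster")
})

test_that("too many missing classifying features abort classification", {
  coh <- test_cohort()
  pb <- pipeline_blocks(coh, 50L)
  m <- suppressWarnings(fit_integrative_model(pb$blocks, K = 5, seed = 1))
  ctr <- train_centroids(m, pb$blocks)
  crippled <- list(expr = pb$blocks$expr[1:10, , drop = FALSE],
                   cn = pb$blocks$cn)
  expect_error(classify_new_samples(ctr, crippled), "missing")
})

test_that("subtypes transfer to an independent cohort from the same process", {
  coh <- test_cohort()
  pb <- pipeline_blocks(coh)
  m <- suppressWarnings(fit_integrative_model(pb$blocks, K = 5, seed = 1))
  ctr <- train_centroids(m, pb$blocks)

  coh2 <- generate_cohort(sim_config(n_tumour = 150L, n_benign = 30L,
                                     n_genes = 1200L, seed = 202L))
  tum2 <- tumour_ids(coh2)
  cn2 <- segments_to_gene_states(coh2$segments, coh2$annotation,
                                 samples = tum2)
  eg2 <- suppressMessages(collapse_probes(coh2$expression))
  shared <- intersect(rownames(eg2), pb$selected)
  pred <- suppressMessages(classify_new_samples(ctr, list(
    expr = eg2[shared, tum2, drop = FALSE],
    cn = cn2[pb$selected, tum2, drop = FALSE] * 1.0
  )))
  cmp <- compare_partitions(pred$cluster, truth_vec(coh2)[pred$sample])
  expect_gte(cmp$ari, 0.85)
})
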