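#' Fit the lasso-penalised joint latent-variable model
#'
#' Models each data block (here copy number and expression over the same
#' tumours) as a linear image of shared latent positions:
#' `X_d = W_d Z + E_d`, with `Z` standard normal of dimension `K - 1` and
#' `E_d` diagonal Gaussian noise. The model is fitted by EM: the E-step
#' gives the posterior mean/covariance of `Z`; the M-step updates the
#' loadings by coordinate descent with an element-wise soft threshold (lasso
#' at `lambda`, scaled per sample) and the noise variances by residual
#' variance. Subtypes are called by k-means on the posterior-mean latent
#' positions.
#'
#' @param blocks Named list of numeric feature x sample matrices sharing the
#'   same sample columns (e.g. `list(expr = ..., cn = ...)`).
#' @param K Number of clusters (>= 2); the latent dimension is `K - 1`.
#' @param lambda Lasso penalty (>= 0) on the loadings, on a per-sample
#'   scale: the objective is the log-likelihood minus
#'   `lambda * n * sum(|W|)`.
#' @param seed Seed controlling initialisation and k-means restarts.
#' @param max_iter,tol EM stopping rule: stop when the relative change in
#'   penalised log-likelihood falls below `tol` or after `max_iter`
#'   iterations.
#' @param init `"svd"` (deterministic, from the stacked data's singular
#'   vectors) or `"random"`.
#' @param standardize Standardize each feature to mean 0, variance 1 before
#'   fitting (the model assumes this).
#' @param nstart_kmeans k-means restarts for the subtype call.
#' @param psi_floor Lower bound on the per-feature noise variances, as a
#'   fraction of the (unit, after standardization) feature variance.
#'   Bounding the uniquenesses away from zero is the standard guard against
#'   Heywood-type degeneracy in heteroscedastic factor models: a feature
#'   whose residual variance collapses (e.g. a discrete CN state perfectly
#'   explained by the latent positions) would otherwise receive unbounded
#'   likelihood weight and dominate the posterior. Recovery is insensitive
#'   to the exact bound over roughly 0.1-0.3.
#' @return An object of class `integrative_model`: loadings `W` (per block),
#'   noise variances `Psi`, posterior-mean latent positions `Z`
#'   (latent_dim x sample), `assignments` (named integer vector),
#'   `variance_explained`, the penalised log-likelihood trace, `converged`
#'   and `n_iter`.
#' @export
fit_integrative_model <- function(blocks, K, lambda = 0.03, seed = 1L,
                                  max_iter = 500L, tol = 1e-6,
                                  init = c("svd", "random"),
                                  standardize = TRUE,
                                  nstart_kmeans = 50L,
                                  psi_floor = 0.2) {
  init <- match.arg(init)
  if (K < 2L) abort("K must be >= 2")
  if (lambda < 0) abort("lambda must be >= 0")
  if (!is.list(blocks) || is.null(names(blocks)) || any(!nzchar(names(blocks)))) {
    abort("`blocks` must be a named list of matrices")
  }
  ns <- vapply(blocks, ncol, integer(1))
  if (length(unique(ns)) != 1L) abort("all blocks must share the same samples")
  samp <- colnames(blocks[[1]])
  for (b in blocks) {
    if (!identical(colnames(b), samp)) abort("block sample columns must match")
  }
  if (standardize) blocks <- lapply(blocks, standardize_rows)

  X <- do.call(rbind, unname(blocks))
  block_of <- rep(names(blocks), vapply(blocks, nrow, integer(1)))
  rownames(X) <- paste(block_of, unlist(lapply(blocks, rownames)), sep = ":")
  p <- nrow(X); n <- ncol(X); q <- K - 1L

  total_var <- rowMeans((X - rowMeans(X))^2)
  fit <- withr::with_seed(child_seed(seed, "em"), {
    em_latent_lasso(X, q, lambda, max_iter, tol, init, psi_floor)
  })

  variance_explained <- max(0, min(1, 1 - sum(fit$psi) / sum(total_var)))
  rownames(fit$W) <- rownames(X)
  names(fit$psi) <- rownames(X)

  Z <- fit$M
  colnames(Z) <- samp
  assignments <- withr::with_seed(child_seed(seed, "kmeans"), {
    kmeans_assign(t(Z), K, nstart_kmeans)
  })
  names(assignments) <- samp

  structure(
    list(
      K = K, latent_dim = q, lambda = lambda,
      W = split.data.frame(fit$W, block_of)[names(blocks)],
      Psi = split(fit$psi, block_of)[names(blocks)],
      Z = Z, assignments = assignments,
      variance_explained = variance_explained,
      loglik_trace = fit$trace, loglik = fit$trace[length(fit$trace)],
      converged = fit$converged, n_iter = fit$n_iter,
      features = lapply(blocks, rownames),
      blocks = names(blocks), n_samples = n, seed = seed
    ),
    class = "integrative_model"
  )
}

# EM for the Gaussian latent model X = W Z + E with diagonal noise and an
# L1 penalty lambda * n * sum(|W|); returns loadings, noise variances,
# posterior means and the penalised log-likelihood trace.
em_latent_lasso <- function(X, q, lambda, max_iter, tol, init, psi_floor) {
  p <- nrow(X); n <- ncol(X)
  row_var <- rowMeans(X^2)  # features are centred

  if (init == "svd") {
    sv <- svd(X, nu = q, nv = 0)
    W <- sv$u %*% diag(sv$d[seq_len(q)] / sqrt(n), q)
  } else {
    W <- matrix(rnorm(p * q, 0, 0.2), p, q)
  }
  psi <- pmax(row_var - rowSums(W^2), 0.1 * row_var + psi_floor)

  c_j <- rowSums(X^2)
  trace <- numeric(0)
  pll_old <- -Inf
  converged <- FALSE
  floored <- FALSE
  it <- 0L

  for (it in seq_len(max_iter)) {
    # E-step: posterior of Z given X
    A <- W / psi                              # p x q
    S <- diag(q) + crossprod(W, A)            # I + W' Psi^-1 W
    Sig_z <- solve(S)
    M <- Sig_z %*% crossprod(A, X)            # q x n posterior means
    M2 <- n * Sig_z + tcrossprod(M)           # sum_i E[z_i z_i']

    # M-step: coordinate-descent lasso update of W (threshold scales with
    # psi because each feature's quadratic loss is weighted by 1/psi)
    B <- X %*% t(M)                           # p x q
    thresh <- lambda * n * psi
    for (sweep_i in 1:3) {
      for (k in seq_len(q)) {
        r_k <- B[, k] - W %*% M2[, k] + W[, k] * M2[k, k]
        W[, k] <- soft_threshold(r_k, thresh) / M2[k, k]
      }
    }

    # M-step: residual noise variances
    WM2 <- W %*% M2
    psi <- (c_j - 2 * rowSums(W * B) + rowSums(WM2 * W)) / n
    if (any(psi < psi_floor)) {
      psi <- pmax(psi, psi_floor)
      floored <- TRUE
    }

    pll <- penalized_loglik(X, W, psi, lambda, c_j)
    if (length(trace) && pll < pll_old - 1e-6 * (abs(pll_old) + 1)) {
      warn(sprintf("penalised log-likelihood decreased at iteration %d", it))
    }
    trace <- c(trace, pll)
    if (is.finite(pll_old) &&
          abs(pll - pll_old) < tol * (abs(pll_old) + 1)) {
      converged <- TRUE
      break
    }
    pll_old <- pll
  }
  if (!converged) warn("EM did not converge within max_iter")
  if (floored) warn(sprintf("noise variances floored at %g", psi_floor))

  list(W = W, psi = psi, M = M, trace = trace, converged = converged,
       n_iter = it)
}

# observed-data log-likelihood of N(0, W W' + diag(psi)) minus the lasso
# penalty, computed via the Woodbury identity
penalized_loglik <- function(X, W, psi, lambda, c_j = rowSums(X^2)) {
  p <- nrow(X); n <- ncol(X); q <- ncol(W)
  A <- W / psi
  S <- diag(q) + crossprod(W, A)
  Sig_z <- solve(S)
  logdet <- sum(log(psi)) + determinant(S, logarithm = TRUE)$modulus[1]
  T_ <- crossprod(A, X)                       # q x n
  tr_term <- sum(c_j / psi) - sum(Sig_z * tcrossprod(T_))
  ll <- -0.5 * (n * p * log(2 * pi) + n * logdet + tr_term)
  ll - lambda * n * sum(abs(W))
}

# k-means with graceful handling of degenerate latent positions
kmeans_assign <- function(points, K, nstart) {
  distinct <- nrow(unique(round(points, 10)))
  if (distinct < K) {
    warn(sprintf(
      "only %d distinct latent positions for K = %d; assigning all samples to one cluster",
      distinct, K))
    return(rep(1L, nrow(points)))
  }
  km <- kmeans(points, centers = K, nstart = nstart, iter.max = 50L)
  as.integer(km$cluster)
}

#' Grid search over cluster number and feature-set size
#'
#' Fits the integrative model over a grid of K (cluster counts) and
#' feature-set sizes, with several randomly initialised restarts per cell;
#' each restart refits on a random subsample of the samples
#' (consensus-clustering style), so the stability score — the mean pairwise
#' Adjusted Rand Index between restarts' assignments on their shared
#' samples — measures how reproducible a partition is under cohort
#' perturbation, not merely under re-initialisation. The lasso penalty is
#' chosen per cell as the value of `lambda_grid` maximising stability. The
#' chosen cell is the smallest K (then smallest feature count) whose
#' stability-weighted variance explained is within 5% of the grid maximum —
#' an elbow rule.
#'
#' @param cn_matrix,expr_matrix Gene x sample matrices over the same
#'   samples (gene-level expression).
#' @param eqtl_features Tibble from [cis_correlations()] used to pick each
#'   feature set via [select_features()].
#' @param K_range Candidate cluster counts (default 2:11).
#' @param n_features_grid Candidate feature-set sizes (default
#'   `seq(100, 1000, by = 100)`, capped at the available features).
#' @param lambda_grid Candidate penalties.
#' @param n_restarts Subsampled random restarts per cell.
#' @param subsample Fraction of samples refitted per restart.
#' @param seed Root seed; every restart derives its own stream.
#' @param max_iter,tol Reduced EM budget for grid fits.
#' @return List with `grid` (one row per cell: K, n_features, lambda,
#'   variance_explained, stability, score, failed), `chosen`
#'   (K, n_features, lambda) and `model`, a final deterministic refit of the
#'   chosen cell.
#' @export
select_model <- function(cn_matrix, expr_matrix, eqtl_features,
                         K_range = 2:11,
                         n_features_grid = seq(100L, 1000L, by = 100L),
                         lambda_grid = c(0.03, 0.1, 0.2),
                         n_restarts = 5L, subsample = 0.7, seed = 1L,
                         max_iter = 60L, tol = 1e-5) {
  n_features_grid <- unique(pmin(n_features_grid, nrow(eqtl_features)))
  samples <- intersect(colnames(cn_matrix), colnames(expr_matrix))
  cells <- tidyr::expand_grid(n_features = n_features_grid, K = K_range)

  rows <- pmap(cells, function(n_features, K) {
    genes <- select_features(eqtl_features, n_features)
    blocks <- list(
      expr = expr_matrix[genes, samples, drop = FALSE],
      cn = cn_matrix[genes, samples, drop = FALSE] * 1.0
    )
    n <- length(samples)
    best <- NULL
    for (lam in lambda_grid) {
      res <- tryCatch({
        fits <- map(seq_len(n_restarts), function(r) {
          sub_seed <- child_seed(seed, paste(n_features, K, lam, r))
          idx <- withr::with_seed(sub_seed, {
            sort(sample(n, max(2L, floor(subsample * n))))
          })
          bl <- lapply(blocks, function(b) b[, idx, drop = FALSE])
          suppressWarnings(fit_integrative_model(
            bl, K = K, lambda = lam, seed = sub_seed,
            max_iter = max_iter, tol = tol, init = "random",
            nstart_kmeans = 10L
          ))
        })
        asg <- map(fits, "assignments")
        pairs <- utils::combn(length(fits), 2)
        stability <- mean(apply(pairs, 2, function(ij) {
          common <- intersect(names(asg[[ij[1]]]), names(asg[[ij[2]]]))
          ari_index(asg[[ij[1]]][common], asg[[ij[2]]][common])
        }))
        ve <- mean(map_dbl(fits, "variance_explained"))
        list(lambda = lam, stability = stability, variance_explained = ve,
             failed = FALSE)
      }, error = function(e) {
        list(lambda = lam, stability = NA_real_, variance_explained = NA_real_,
             failed = TRUE)
      })
      if (is.null(best) ||
            (!res$failed && (best$failed || res$stability > best$stability))) {
        best <- res
      }
    }
    tibble(K = K, n_features = n_features, lambda = best$lambda,
           variance_explained = best$variance_explained,
           stability = best$stability, failed = best$failed)
  }) |> list_rbind()

  rows <- rows |> mutate(score = .data$stability * .data$variance_explained)
  ok <- rows |> filter(!.data$failed, is.finite(.data$score))
  if (!nrow(ok)) abort("all grid cells failed")
  eligible <- ok |> filter(.data$score >= 0.95 * max(.data$score))
  chosen <- eligible |> arrange(.data$K, .data$n_features) |> dplyr::slice(1L)

  genes <- select_features(eqtl_features, chosen$n_features)
  blocks <- list(
    expr = expr_matrix[genes, samples, drop = FALSE],
    cn = cn_matrix[genes, samples, drop = FALSE] * 1.0
  )
  model <- fit_integrative_model(blocks, K = chosen$K, lambda = chosen$lambda,
                                 seed = seed)
  list(grid = rows,
       chosen = list(K = chosen$K, n_features = chosen$n_features,
                     lambda = chosen$lambda),
       model = model)
}

#' Train per-subtype centroids for classifier transfer
#'
#' Stores the per-cluster mean of the standardized, concatenated CN +
#' expression feature vector, together with the training-cohort scaling
#' parameters, so a validation cohort can be partitioned without refitting.
#'
#' @param model A fitted [fit_integrative_model()] object.
#' @param blocks Named list of the same (unstandardized) feature x sample
#'   blocks the model was trained on.
#' @return Object of class `subtype_centroids`.
#' @export
train_centroids <- function(model, blocks) {
  samp <- names(model$assignments)
  std <- lapply(blocks, function(b) standardize_rows(b[, samp, drop = FALSE]))
  X <- do.call(rbind, unname(std))
  feature_key <- unlist(lapply(names(blocks), function(nm) {
    paste(nm, rownames(blocks[[nm]]), sep = ":")
  }))
  rownames(X) <- feature_key

  K <- model$K
  counts <- tabulate(model$assignments, nbins = K)
  if (any(counts == 0L)) {
    abort(sprintf("empty cluster(s): %s", paste(which(counts == 0L), collapse = ", ")))
  }
  centroids <- vapply(seq_len(K), function(k) {
    rowMeans(X[, model$assignments == k, drop = FALSE])
  }, numeric(nrow(X)))
  colnames(centroids) <- paste0("cluster", seq_len(K))

  structure(
    list(
      centroids = centroids,
      center = unlist(lapply(std, attr, "center")),
      scale = unlist(lapply(std, attr, "scale")),
      feature_key = feature_key,
      blocks = names(blocks), K = K
    ),
    class = "subtype_centroids"
  )
}

#' Assign new samples to trained subtypes by nearest centroid
#'
#' New samples are standardized with the training cohort's per-feature
#' center/scale and assigned to the Euclidean-nearest centroid. Classifying
#' features missing from the new cohort are imputed to 0 (the training
#' mean) and counted; more than 20% missing is an error. Exact distance
#' ties resolve to the lowest-indexed cluster and are logged.
#'
#' @param centroids A [train_centroids()] object.
#' @param blocks Named list of feature x sample matrices for the new cohort
#'   (same block names as training).
#' @param max_missing Maximum tolerated fraction of missing classifying
#'   features.
#' @return Tibble with `sample`, `cluster`, `distance`; the full
#'   sample x centroid distance matrix is in attribute `distances`, the
#'   imputed features in `missing_features`.
#' @export
classify_new_samples <- function(centroids, blocks, max_missing = 0.2) {
  if (!identical(sort(names(blocks)), sort(centroids$blocks))) {
    abort("block names must match the training blocks")
  }
  samp <- colnames(blocks[[centroids$blocks[1]]])
  if (is.null(samp) || !length(samp)) abort("new cohort has no samples")
  p <- length(centroids$feature_key)
  X <- matrix(NA_real_, nrow = p, ncol = length(samp),
              dimnames = list(centroids$feature_key, samp))
  for (nm in centroids$blocks) {
    b <- blocks[[nm]]
    key <- paste(nm, rownames(b), sep = ":")
    hit <- key %in% centroids$feature_key
    X[key[hit], ] <- b[hit, samp, drop = FALSE]
  }
  missing <- rowSums(is.na(X)) > 0
  if (mean(missing) > max_missing) {
    abort(sprintf("%.0f%% of classifying features missing (limit %.0f%%)",
                  100 * mean(missing), 100 * max_missing))
  }
  if (any(missing)) {
    inform(sprintf("classify_new_samples: %d classifying feature(s) missing; imputed to training mean",
                   sum(missing)))
  }
  Xs <- (X - centroids$center) / centroids$scale
  Xs[is.na(Xs)] <- 0

  d2 <- vapply(seq_len(centroids$K), function(k) {
    colSums((Xs - centroids$centroids[, k])^2)
  }, numeric(ncol(Xs)))
  d2 <- matrix(d2, ncol = centroids$K,
               dimnames = list(samp, colnames(centroids$centroids)))
  cluster <- apply(d2, 1L, which.min)
  ties <- apply(d2, 1L, function(r) sum(r == min(r)) > 1L)
  if (any(ties)) {
    inform(sprintf("distance ties for %d sample(s); lowest-indexed cluster kept",
                   sum(ties)))
  }
  out <- tibble(sample = samp, cluster = as.integer(cluster),
                distance = sqrt(d2[cbind(seq_along(samp), cluster)]))
  attr(out, "distances") <- sqrt(d2)
  attr(out, "missing_features") <- centroids$feature_key[missing]
  out
}
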