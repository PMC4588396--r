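#' Per-gene linear model of expression across subtypes and benign tissue
#'
#' Fits an ordinary least-squares one-way model per gene (group means) and
#' forms the contrast of each subtype against the pooled benign reference.
#'
#' @param expr_matrix Gene x sample log2 matrix.
#' @param groups Factor-like group label per sample column; one level must
#'   be `reference` (the benign group).
#' @param reference Name of the reference level (default `"benign"`).
#' @return List with `coef` (gene x group means), `log2_fc` (gene x
#'   contrast), `s2` residual variances, `df` residual degrees of freedom,
#'   `group_n` sizes, `reference`.
#' @export
fit_linear_de <- function(expr_matrix, groups, reference = "benign") {
  stopifnot_matrix(expr_matrix, "expr_matrix")
  groups <- factor(groups)
  if (length(groups) != ncol(expr_matrix)) {
    abort("`groups` must label every sample column")
  }
  if (!reference %in% levels(groups)) {
    abort(sprintf("reference group '%s' not present", reference))
  }
  if (any(table(groups) < 2L)) {
    small <- names(which(table(groups) < 2L))
    abort(sprintf("each group needs >= 2 samples (too small: %s)",
                  paste(small, collapse = ", ")))
  }
  design <- stats::model.matrix(~ 0 + groups)
  colnames(design) <- levels(groups)
  if (qr(design)$rank < ncol(design)) {
    abort("singular design matrix")  # unreachable for a one-way layout
  }

  # one-way OLS: coefficients are group means, residuals pool within-group
  n_g <- table(groups)
  means <- vapply(levels(groups), function(g) {
    rowMeans(expr_matrix[, groups == g, drop = FALSE])
  }, numeric(nrow(expr_matrix)))
  fitted <- means[, as.character(groups), drop = FALSE]
  rss <- rowSums((expr_matrix - fitted)^2)
  df <- ncol(expr_matrix) - nlevels(groups)
  s2 <- rss / df

  contrasts <- setdiff(levels(groups), reference)
  log2_fc <- means[, contrasts, drop = FALSE] - means[, reference]
  colnames(log2_fc) <- paste0(contrasts, "_vs_", reference)

  list(coef = means, log2_fc = log2_fc, s2 = s2, df = df,
       group_n = as.integer(n_g), group_names = levels(groups),
       reference = reference)
}

#' Empirical-Bayes shrinkage of per-gene variances and moderated t-tests
#'
#' Estimates a scaled inverse-chi-square prior for the residual variances by
#' moment-matching the distribution of `log(s^2)` (closed-form moments of
#' the log-F), shrinks each gene's variance to
#' `(d0*s0^2 + df*s^2) / (d0 + df)`, and forms moderated t-statistics with
#' `d0 + df` degrees of freedom. P-values are Benjamini-Hochberg adjusted
#' within each contrast.
#'
#' @param fit Output of [fit_linear_de()].
#' @param d0,s0_sq Optional forced hyperparameters (`d0 = 0` recovers the
#'   ordinary t-test; `d0 = Inf` shrinks every variance to `s0_sq`).
#' @return Tibble with one row per gene per contrast: `gene_id`, `contrast`,
#'   `log2_fc`, `t`, `p_value`, `adj_p`; shrinkage hyperparameters are in
#'   attribute `shrinkage` (`d0`, `s0_sq`).
#' @export
eb_shrink <- function(fit, d0 = NULL, s0_sq = NULL) {
  s2 <- fit$s2
  df <- fit$df
  if (is.null(d0) || is.null(s0_sq)) {
    if (length(s2) < 10L) abort("need >= 10 genes to estimate the prior")
    est <- fit_variance_prior(s2, df)
    d0 <- d0 %||% est$d0
    s0_sq <- s0_sq %||% est$s0_sq
  }

  s2_mod <- if (is.infinite(d0)) {
    rep(s0_sq, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s0_sq + df * s2) / (d0 + df)
  }
  df_mod <- if (is.infinite(d0)) 1e6 else d0 + df

  # contrast variance factor: var(mean_a - mean_ref) = s2 * (1/n_a + 1/n_ref)
  n <- setNames(fit$group_n, fit$group_names)
  contrasts <- colnames(fit$log2_fc)
  levels_a <- sub(paste0("_vs_", fit$reference, "$"), "", contrasts)
  out <- imap(setNames(levels_a, contrasts), function(a, ctr) {
    v <- 1 / n[[a]] + 1 / n[[fit$reference]]
    tstat <- fit$log2_fc[, ctr] / sqrt(s2_mod * v)
    p <- 2 * pt(-abs(tstat), df = df_mod)
    tibble(gene_id = names(fit$s2) %||% rownames(fit$log2_fc),
           contrast = ctr, log2_fc = unname(fit$log2_fc[, ctr]),
           t = unname(tstat), p_value = unname(p),
           adj_p = p.adjust(unname(p), method = "BH"))
  }) |> list_rbind()

  attr(out, "shrinkage") <- list(d0 = d0, s0_sq = s0_sq)
  out
}

# moment-matching estimator of the scaled inverse-chi-square prior for
# gene-wise variances, via the mean/variance of log(s^2)
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  e_bar <- mean(e)
  v <- var(e) * (length(e) - 1) / length(e)
  excess <- v - trigamma(df / 2)
  if (!is.finite(excess) || excess <= 0) {
    return(list(d0 = Inf, s0_sq = exp(e_bar)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0_sq <- exp(e_bar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton inversion of the trigamma function on (0, Inf)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) < 1e-8 * y) break
  }
  y
}

#' Threshold differentially expressed genes by fold change
#'
#' @param de Tibble from [eb_shrink()].
#' @param fc_cut Positive log2 fold-change cut (1, 1.5 and 2 are the
#'   conventional choices).
#' @param strict If `FALSE` (default) the boundary is inclusive
#'   (`|log2FC| >= fc_cut`); `TRUE` makes it strict.
#' @return Tibble with `contrast`, `gene_id`, `log2_fc`, `direction`
#'   ("up"/"down").
#' @export
threshold_degs <- function(de, fc_cut, strict = FALSE) {
  if (fc_cut <= 0) abort("fc_cut must be > 0")
  keep <- if (strict) abs(de$log2_fc) > fc_cut else abs(de$log2_fc) >= fc_cut
  de[keep, ] |>
    mutate(direction = ifelse(.data$log2_fc > 0, "up", "down")) |>
    select("contrast", "gene_id", "log2_fc", "direction")
}
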