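#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_point geom_col
#'   geom_errorbar labs scale_y_continuous facet_wrap theme_minimal
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
print.integrative_model <- function(x, ...) {
  cat(sprintf(
    "Integrative latent-variable model: K = %d (latent dim %d), lambda = %g\n",
    x$K, x$latent_dim, x$lambda))
  cat(sprintf("  %d samples, blocks: %s\n", x$n_samples,
              paste(sprintf("%s (%d features)", x$blocks,
                            vapply(x$features, length, integer(1))),
                    collapse = ", ")))
  cat(sprintf("  variance explained = %.3f, %sconverged in %d iterations\n",
              x$variance_explained, if (x$converged) "" else "NOT ",
              x$n_iter))
  cat("  cluster sizes:", paste(tabulate(x$assignments, x$K), collapse = ", "),
      "\n")
  invisible(x)
}

#' Tidy the loadings of an integrative model
#'
#' @param x A [fit_integrative_model()] object.
#' @param ... Unused.
#' @return Tibble with one row per feature per latent dimension: `block`,
#'   `feature_id`, `dimension`, `loading`, `noise_variance`.
#' @export
tidy.integrative_model <- function(x, ...) {
  imap(x$W, function(w, blk) {
    as_tibble(w, .name_repair = ~paste0("dim", seq_along(.x))) |>
      mutate(block = blk,
             feature_id = sub(paste0("^", blk, ":"), "", rownames(w)),
             noise_variance = unname(x$Psi[[blk]])) |>
      tidyr::pivot_longer(dplyr::starts_with("dim"), names_to = "dimension",
                          names_prefix = "dim", values_to = "loading") |>
      mutate(dimension = as.integer(.data$dimension)) |>
      select("block", "feature_id", "dimension", "loading", "noise_variance")
  }) |> list_rbind()
}

#' One-row model summary
#'
#' @inheritParams tidy.integrative_model
#' @return Tibble with `K`, `latent_dim`, `lambda`, `n_samples`,
#'   `variance_explained`, `loglik`, `n_iter`, `converged`,
#'   `n_active_loadings`.
#' @export
glance.integrative_model <- function(x, ...) {
  tibble(
    K = x$K, latent_dim = x$latent_dim, lambda = x$lambda,
    n_samples = x$n_samples,
    variance_explained = x$variance_explained,
    loglik = x$loglik, n_iter = x$n_iter, converged = x$converged,
    n_active_loadings = sum(vapply(x$W, function(w) sum(w != 0), numeric(1)))
  )
}

#' Plot samples in latent space, coloured by subtype
#'
#' @param object A [fit_integrative_model()] object.
#' @param dims Two latent dimensions to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.integrative_model <- function(object, dims = c(1L, 2L), ...) {
  if (object$latent_dim < 2L) dims <- c(1L, 1L)
  df <- tibble(
    x = object$Z[dims[1], ], y = object$Z[dims[2], ],
    cluster = factor(object$assignments)
  )
  ggplot(df, aes(.data$x, .data$y, colour = .data$cluster)) +
    geom_point(size = 2) +
    labs(x = sprintf("latent dim %d", dims[1]),
         y = sprintf("latent dim %d", dims[2]),
         colour = "subtype") +
    theme_minimal()
}

#' Kaplan-Meier step plot
#'
#' @param object A `km_fit` tibble from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot of the survival curves per group.
#' @export
autoplot.km_fit <- function(object, ...) {
  start <- object |>
    distinct(.data$group) |>
    mutate(time = 0, surv = 1)
  df <- bind_rows(start, object |> select("group", "time", "surv")) |>
    arrange(.data$group, .data$time)
  ggplot(df, aes(.data$time, .data$surv, colour = .data$group)) +
    geom_step() +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "months", y = "relapse-free fraction", colour = "group") +
    theme_minimal()
}

#' Forest-style plot of Cox hazard ratios
#'
#' Hazard ratios with the 0.90, 0.95 and 0.99 Wald intervals overlaid.
#'
#' @param object A `cox_fit` tibble from [cox_fit()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cox_fit <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(.data$hr, .data$term)) +
    geom_errorbar(aes(xmin = .data$conf_low_99, xmax = .data$conf_high_99),
                  width = 0, linewidth = 0.3, alpha = 0.5) +
    geom_errorbar(aes(xmin = .data$conf_low_95, xmax = .data$conf_high_95),
                  width = 0, linewidth = 0.7) +
    geom_errorbar(aes(xmin = .data$conf_low_90, xmax = .data$conf_high_90),
                  width = 0, linewidth = 1.2) +
    geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    labs(x = "hazard ratio (log scale)", y = NULL) +
    theme_minimal()
}

#' @export
print.signature_score <- function(x, ...) {
  cat(sprintf("Signature score: %d genes, logrank chi-square = %.3f (p = %.3g)\n",
              x$n_matched, x$chi_square, x$p_value))
  if (!is.null(x$percentile)) {
    cat(sprintf("  percentile vs %d random signatures: %.1f (%d strictly better)\n",
                x$null_summary$R, x$percentile, x$n_better))
  }
  invisible(x)
}
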