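#' Build a survival analysis table from clinical data
#'
#' Restricts to tumour samples with observed follow-up and attaches the
#' conventional risk dichotomizations: `gleason_high` (>= 4 + 3),
#' `psa_high` (> 10 ng/ml; exactly 10 counts as low).
#'
#' @param clinical Clinical tibble.
#' @param assignments Optional named cluster vector (sample -> cluster) to
#'   attach as `cluster`.
#' @return Tibble with `sample`, `time`, `event`, dichotomized covariates
#'   and optionally `cluster`.
#' @export
survival_table <- function(clinical, assignments = NULL) {
  out <- clinical |>
    filter(.data$tissue == "tumour",
           !is.na(.data$time_to_bcr), !is.na(.data$bcr_event)) |>
    mutate(
      time = .data$time_to_bcr,
      event = .data$bcr_event,
      gleason_high = dplyr::case_when(
        is.na(.data$gleason_primary) | is.na(.data$gleason_secondary) ~ NA,
        .data$gleason_primary + .data$gleason_secondary > 7 ~ TRUE,
        .data$gleason_primary + .data$gleason_secondary == 7 ~
          .data$gleason_primary >= 4,
        .default = FALSE
      ),
      psa_high = .data$psa > 10
    ) |>
    select("sample", "time", "event", "gleason_high", "psa_high",
           "ece", "psm")
  if (!is.null(assignments)) {
    out <- out |>
      mutate(cluster = unname(assignments[.data$sample])) |>
      filter(!is.na(.data$cluster))
  }
  out
}

#' Kaplan-Meier product-limit estimate per group
#'
#' Censored subjects leave the risk set at their censoring time; at tied
#' times events are processed before censorings (the product-limit
#' convention).
#'
#' @param data Tibble with `time`, `event` and optionally a grouping column.
#' @param group Name of the grouping column, or `NULL` for a single curve.
#' @return Tibble of class `km_fit`: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (each curve implicitly starts at S(0) = 1).
#' @export
km_estimate <- function(data, group = NULL) {
  if (!nrow(data)) abort("no subjects")
  grp <- if (is.null(group)) factor(rep("all", nrow(data))) else factor(data[[group]])
  fit <- survival::survfit(
    survival::Surv(data$time, data$event) ~ grp
  )
  sm <- summary(fit, censored = TRUE)
  g <- if (is.null(sm$strata)) rep(levels(grp)[1], length(sm$time)) else {
    sub("^grp=", "", as.character(sm$strata))
  }
  out <- tibble(
    group = g, time = sm$time, n_risk = sm$n.risk,
    n_event = sm$n.event, n_censor = sm$n.censor, surv = sm$surv
  )
  class(out) <- c("km_fit", class(out))
  out
}

#' K-group logrank test
#'
#' At each distinct event time the observed events per group are compared
#' with their hypergeometric expectation given the risk sets; the
#' chi-square statistic uses the standard variance estimate with K - 1
#' degrees of freedom.
#'
#' @param data Tibble with `time`, `event` and a grouping column.
#' @param group Name of the grouping column.
#' @return Tibble with `chi_square`, `df`, `p_value`, `n`, `n_event`.
#' @export
logrank_test <- function(data, group = "cluster") {
  grp <- factor(data[[group]])
  if (nlevels(grp) < 2L) abort("need >= 2 groups")
  if (any(table(grp) == 0L)) abort("a group has zero subjects")
  if (sum(data$event) < 1L) abort("need >= 1 event")
  sd_ <- survival::survdiff(survival::Surv(data$time, data$event) ~ grp)
  df <- nlevels(grp) - 1L
  tibble(
    chi_square = unname(sd_$chisq), df = df,
    p_value = pchisq(unname(sd_$chisq), df = df, lower.tail = FALSE),
    n = nrow(data), n_event = sum(data$event)
  )
}

#' Pooled extremes logrank contrast
#'
#' Ranks groups by their observed event fraction, pools the two
#' highest-risk and the two lowest-risk groups, drops any middle groups,
#' and runs a two-group logrank on the pooled extremes.
#'
#' @inheritParams logrank_test
#' @return As [logrank_test()], plus `high_groups` and `low_groups`
#'   (comma-separated labels).
#' @export
logrank_extremes <- function(data, group = "cluster") {
  grp <- factor(data[[group]])
  if (nlevels(grp) < 4L) abort("need >= 4 groups to pool two against two")
  risk <- data |>
    group_by(g = grp) |>
    summarise(frac = mean(.data$event)) |>
    arrange(desc(.data$frac))
  high <- as.character(risk$g[1:2])
  low <- as.character(risk$g[(nrow(risk) - 1):nrow(risk)])
  sub <- data |>
    mutate(pool = dplyr::case_when(
      as.character(grp) %in% high ~ "high",
      as.character(grp) %in% low ~ "low",
      .default = NA_character_
    )) |>
    filter(!is.na(.data$pool))
  out <- logrank_test(sub, "pool")
  out$high_groups <- paste(high, collapse = ",")
  out$low_groups <- paste(low, collapse = ",")
  out
}

#' Cox proportional-hazards fit with Wald intervals
#'
#' Maximizes the partial likelihood (Efron tie correction by default) and
#' reports per-covariate log-hazard coefficients, hazard ratios, Wald
#' confidence intervals at the 0.9/0.95/0.99 levels and Wald p-values.
#' Unless overridden, the fit refuses to run with fewer than `min_epv`
#' events per estimated parameter.
#'
#' @param data Survival tibble (see [survival_table()]).
#' @param covariates Character vector of covariate column names; factors and
#'   logicals are expanded by the usual treatment coding.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param min_epv,override_epv Events-per-variable guard (see
#'   [epv_check()]).
#' @return Tibble of class `cox_fit`: `term`, `estimate` (log HR), `hr`,
#'   `conf_low_90`/`conf_high_90`, `..._95`, `..._99`, `p_value`; the
#'   underlying `coxph` fit is in attribute `fit`.
#' @export
cox_fit <- function(data, covariates, ties = c("efron", "breslow"),
                    min_epv = 10, override_epv = FALSE) {
  ties <- match.arg(ties)
  cc <- data[stats::complete.cases(data[, c("time", "event", covariates)]), ]
  form <- stats::as.formula(
    paste("survival::Surv(time, event) ~", paste(covariates, collapse = " + "))
  )
  n_params <- ncol(stats::model.matrix(form, data = cc)) - 1L
  chk <- epv_check(sum(cc$event), n_params, min_epv)
  if (!chk$pass && !override_epv) {
    abort(paste0(chk$message, " (set override_epv = TRUE to force)"))
  }
  fit <- survival::coxph(form, data = cc, ties = ties)
  if (any(is.na(stats::coef(fit)))) abort("Cox fit produced undefined coefficients")
  if (!is.null(fit$info) && isTRUE(grepl("infinite", fit$info))) {
    abort("monotone likelihood (perfect separation) in Cox fit")
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(abs(beta) > 15)) {
    abort("Cox coefficients diverged; likely perfect separation")
  }
  ci <- function(level) qnorm(1 - (1 - level) / 2) * se
  out <- tibble(
    term = names(beta), estimate = unname(beta), hr = exp(unname(beta)),
    conf_low_90 = exp(unname(beta - ci(0.90))),
    conf_high_90 = exp(unname(beta + ci(0.90))),
    conf_low_95 = exp(unname(beta - ci(0.95))),
    conf_high_95 = exp(unname(beta + ci(0.95))),
    conf_low_99 = exp(unname(beta - ci(0.99))),
    conf_high_99 = exp(unname(beta + ci(0.99))),
    p_value = 2 * stats::pnorm(-abs(unname(beta) / se))
  )
  attr(out, "fit") <- fit
  attr(out, "n") <- nrow(cc)
  class(out) <- c("cox_fit", class(out))
  out
}

#' Events-per-variable safeguard for multivariable survival models
#'
#' @param n_events Number of observed events.
#' @param n_params Number of model parameters.
#' @param min_epv Minimum events per parameter (default 10).
#' @return List with `pass`, `epv`, `message`.
#' @export
epv_check <- function(n_events, n_params, min_epv = 10) {
  if (n_params <= 0L) abort("n_params must be > 0")
  if (n_events < 0L) abort("n_events must be >= 0")
  epv <- n_events / n_params
  pass <- epv >= min_epv
  msg <- if (pass) {
    sprintf("%.2f events per variable (>= %g): ok", epv, min_epv)
  } else {
    sprintf(paste("%.2f events per variable (< %g): too few events;",
                  "consider combining cohorts to gain events"),
            epv, min_epv)
  }
  list(pass = pass, epv = epv, message = msg)
}
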