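test_that("Kaplan-Meier matches the hand product-limit computation", {
  d <- tibble::tibble(time = c(1, 2, 3), event = 1L)
  km <- km_estimate(d)
  expect_equal(km$surv, c(2/3, 1/3, 0))
  # no events: flat at 1
  d2 <- tibble::tibble(time = c(5, 7), event = 0L)
  expect_true(all(km_estimate(d2)$surv == 1))
  # general agreement with the independent oracle under censoring
  withr::with_seed(3, {
    d3 <- tibble::tibble(time = round(rexp(60, 0.1), 1) + 0.1,
                         event = rbinom(60, 1, 0.7))
    km3 <- km_estimate(d3)
    orc <- km_oracle(d3$time, d3$event)
    at_events <- km3[km3$n_event > 0, ]
    expect_equal(at_events$surv, orc$surv[match(at_events$time, orc$time)])
  })
})

test_that("KM curves are non-increasing step functions in [0,1]", {
  withr::with_seed(5, {
    d <- tibble::tibble(time = rexp(80, 0.05), event = rbinom(80, 1, 0.6),
                        grp = rep(c("a", "b"), 40))
    km <- km_estimate(d, "grp")
    for (g in c("a", "b")) {
      s <- km$surv[km$group == g]
      expect_true(all(diff(s) <= 1e-12))
      expect_true(all(s >= 0 & s <= 1))
    }
  })
})

test_that("a censoring tied with an event leaves the censored subject at risk", {
  # event and censoring both at t = 2: the censored subject counts in the
  # risk set for the event at 2
  d <- tibble::tibble(time = c(2, 2, 3), event = c(1L, 0L, 1L))
  km <- km_estimate(d)
  expect_equal(km$surv[km$time == 2 & km$n_event == 1], 1 - 1/3)
})

test_that("logrank equals the exhaustive O-E/V computation", {
  # 6-subject worked example with censoring and a tie
  d <- tibble::tibble(
    time = c(1, 2, 2, 3, 4, 5),
    event = c(1L, 1L, 0L, 1L, 1L, 0L),
    grp = c("a", "a", "b", "b", "a", "b")
  )
  got <- logrank_test(d, "grp")
  orc <- logrank_oracle(d$time, d$event, d$grp)
  expect_equal(got$chi_square, orc$chi_square, tolerance = 1e-10)
  expect_equal(got$df, orc$df)
  # three-group case against the same oracle
  withr::with_seed(11, {
    d3 <- tibble::tibble(time = rexp(45, 0.1), event = rbinom(45, 1, 0.8),
                         grp = rep(c("a", "b", "c"), 15))
    expect_equal(logrank_test(d3, "grp")$chi_square,
                 logrank_oracle(d3$time, d3$event, d3$grp)$chi_square,
                 tolerance = 1e-8)
  })
})

test_that("two identical groups give a zero logrank statistic", {
  half <- tibble::tibble(time = c(1, 3, 4, 6), event = c(1L, 1L, 0L, 1L))
  d <- dplyr::bind_rows(dplyr::mutate(half, grp = "a"),
                        dplyr::mutate(half, grp = "b"))
  expect_equal(logrank_test(d, "grp")$chi_square, 0, tolerance = 1e-12)
  expect_error(logrank_test(dplyr::mutate(d, event = 0L), "grp"), "event")
})

test_that("logrank is powered for a 3-fold hazard difference", {
  withr::with_seed(21, {
    hits <- replicate(200, {
      t1 <- rexp(60, 0.02); t2 <- rexp(60, 0.06)
      cens <- stats::quantile(c(t1, t2), 0.6)  # ~40% censoring
      d <- tibble::tibble(
        time = pmin(c(t1, t2), cens),
        event = as.integer(c(t1, t2) <= cens),
        grp = rep(c("a", "b"), each = 60)
      )
      logrank_test(d, "grp")$p_value < 0.05
    })
    expect_gte(mean(hits), 0.9)
  })
})

test_that("extreme-group pooling contrasts top-2 against bottom-2 risk groups", {
  withr::with_seed(23, {
    haz <- c(0.08, 0.005, 0.06, 0.004, 0.02)
    d <- purrr::list_rbind(purrr::imap(haz, function(h, k) {
      t <- rexp(40, h)
      tibble::tibble(time = pmin(t, 100), event = as.integer(t <= 100),
                     cluster = k)
    }))
    out <- logrank_extremes(d)
    expect_equal(out$df, 1L)
    expect_setequal(strsplit(out$high_groups, ",")[[1]], c("1", "3"))
    expect_setequal(strsplit(out$low_groups, ",")[[1]], c("2", "4"))
    expect_lt(out$p_value, 0.01)
  })
})

test_that("Cox estimates recover a known log-hazard ratio", {
  withr::with_seed(31, {
    est <- replicate(60, {
      x <- rep(c(0, 1), each = 150)
      t <- rexp(300, 0.02 * exp(1.0 * x))
      cens <- stats::quantile(t, 0.7)
      d <- tibble::tibble(time = pmin(t, cens), event = as.integer(t <= cens),
                          x = x)
      cox_fit(d, "x")$estimate
    })
    expect_gt(mean(est), 0.85)
    expect_lt(mean(est), 1.15)
  })
})

test_that("null covariates give calibrated Wald intervals", {
  withr::with_seed(37, {
    cover <- replicate(200, {
      d <- tibble::tibble(time = rexp(120, 0.05),
                          event = rbinom(120, 1, 0.8),
                          x = rnorm(120))
      fit <- cox_fit(d, "x")
      fit$conf_low_95 < 1 && fit$conf_high_95 > 1
    })
    expect_gt(mean(cover), 0.90)
    expect_lt(mean(cover), 0.99)
  })
})

test_that("the Cox score test at beta = 0 equals the logrank chi-square", {
  withr::with_seed(41, {
    t <- round(rexp(50, 0.1), 6)  # continuous: no ties
    d <- tibble::tibble(time = t, event = rbinom(50, 1, 0.8),
                        x = rep(c(0, 1), 25))
    fit <- attr(cox_fit(d, "x"), "fit")
    lr <- logrank_test(d, "x")
    expect_equal(unname(fit$score), lr$chi_square, tolerance = 1e-6)
  })
})

test_that("Efron and Breslow tie corrections agree when there are no ties", {
  withr::with_seed(43, {
    d <- tibble::tibble(time = rexp(60, 0.1), event = rbinom(60, 1, 0.7),
                        x = rnorm(60))
    a <- cox_fit(d, "x", ties = "efron")
    b <- cox_fit(d, "x", ties = "breslow")
    expect_equal(a$estimate, b$estimate, tolerance = 1e-10)
  })
})

test_that("the events-per-variable guard follows the 10-per-parameter rule", {
  expect_false(epv_check(21, 4)$pass)   # 5.25 < 10
  expect_true(epv_check(69, 4)$pass)    # 17.25 >= 10
  expect_match(epv_check(21, 4)$message, "combining cohorts")
  expect_error(epv_check(10, 0), "n_params")
  # cox_fit refuses under the guard unless overridden
  withr::with_seed(47, {
    d <- tibble::tibble(time = rexp(20, 0.05), event = rbinom(20, 1, 0.3),
                        x = rnorm(20))
    expect_error(cox_fit(d, "x"), "events per variable")
    expect_s3_class(cox_fit(d, "x", override_epv = TRUE), "cox_fit")
  })
})

test_that("clinical dichotomizations follow the printed conventions", {
  cl <- tibble::tibble(
    sample = paste0("t", 1:4), tissue = "tumour", cohort = "c", batch = "b1",
    cellularity_pct = 50, psa = c(9, 10, 10.5, NA),
    gleason_primary = c(3L, 4L, 3L, 4L), gleason_secondary = c(4L, 3L, 3L, 5L),
    stage = "T2", ece = 0L, psm = 0L,
    time_to_bcr = c(10, 20, 30, 40), bcr_event = c(1L, 0L, 1L, 0L)
  )
  sv <- survival_table(cl)
  expect_equal(sv$psa_high, c(FALSE, FALSE, TRUE, NA))  # 10 goes to low
  expect_equal(sv$gleason_high, c(FALSE, TRUE, FALSE, TRUE))  # 4+3 high, 3+4 low
})
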