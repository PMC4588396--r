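test_that("ARI and VII satisfy their identities", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(compare_partitions(a, a), tibble::tibble(
    ari = 1, vii = 0, vii_unit = "bits"
  ))
  relab <- c(7, 7, 5, 5, 9, 9)  # same partition, different labels
  cmp <- compare_partitions(a, relab)
  expect_equal(cmp$ari, 1)
  expect_equal(cmp$vii, 0)
  expect_error(compare_partitions(a, a[-1]), "same samples")
  expect_error(compare_partitions(1, 1), ">= 2 samples")
})

test_that("ARI equals brute-force pair enumeration on a 6-sample table", {
  # contingency table [[2,1],[1,2]]
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 1, 2, 2)
  cmp <- compare_partitions(a, b)
  expect_equal(cmp$ari, ari_oracle(a, b), tolerance = 1e-12)
  # random partitions against the oracle and the reference implementation
  withr::with_seed(11, {
    for (i in 1:10) {
      x <- sample(1:3, 12, replace = TRUE)
      y <- sample(1:4, 12, replace = TRUE)
      got <- compare_partitions(x, y)$ari
      expect_equal(got, ari_oracle(x, y), tolerance = 1e-12)
      expect_equal(got, mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
    }
  })
})

test_that("VII is a metric on partitions", {
  withr::with_seed(13, {
    for (i in 1:20) {
      x <- sample(1:3, 15, replace = TRUE)
      y <- sample(1:3, 15, replace = TRUE)
      z <- sample(1:4, 15, replace = TRUE)
      vxy <- compare_partitions(x, y)$vii
      vyz <- compare_partitions(y, z)$vii
      vxz <- compare_partitions(x, z)$vii
      expect_gte(vxy, 0)
      expect_lte(vxz, vxy + vyz + 1e-12)  # triangle inequality
      expect_equal(vxy, compare_partitions(y, x)$vii)  # symmetry
    }
  })
})

sig_cohort <- function(seed = 303L, hr = 3) {
  # expression with a latent 2-group prognostic structure on genes 1..50
  withr::with_seed(seed, {
    n <- 160
    grp <- rep(c(1, 2), each = n / 2)
    m <- matrix(rnorm(1000 * n, 8, 1), 1000, n,
                dimnames = list(sprintf("g%04d", 1:1000), sprintf("s%03d", 1:n)))
    m[1:50, grp == 2] <- m[1:50, grp == 2] + 1.5
    haz <- 0.01 * ifelse(grp == 2, hr, 1)
    t <- rexp(n, haz)
    surv <- tibble::tibble(sample = colnames(m),
                           time = pmin(t, 100),
                           event = as.integer(t <= 100))
    list(expr = m, surv = surv, genes = rownames(m)[1:50], grp = grp)
  })
}

test_that("signature scoring is deterministic and recovers planted structure", {
  sc <- sig_cohort()
  a <- score_signature(sc$genes, sc$expr, sc$surv, seed = 5)
  b <- score_signature(sc$genes, sc$expr, sc$surv, seed = 5)
  expect_identical(a$chi_square, b$chi_square)
  expect_identical(a$partition, b$partition)
  expect_lt(a$p_value, 0.01)
  # the induced 2-group split matches the latent groups
  expect_gte(compare_partitions(a$partition, sc$grp)$ari, 0.8)
})

test_that("signature scoring handles degenerate inputs", {
  sc <- sig_cohort()
  expect_message(dup <- score_signature(c(sc$genes, sc$genes[1]),
                                        sc$expr, sc$surv), "duplicate")
  expect_equal(dup$n_matched, 50L)
  expect_error(score_signature(c("nope1", "nope2", sc$genes[1]),
                               sc$expr, sc$surv), "fewer than 3")
})

test_that("a planted prognostic signature beats random signatures", {
  sc <- sig_cohort()
  res <- random_signature_null(sc$genes, sc$expr, sc$surv, R = 100L,
                               seed = 7L)
  expect_gte(res$percentile, 95)
  expect_equal(res$percentile,
               100 * sum(attr(res, "null_chisq") <= res$chi_square) / 100)
})

test_that("degenerate null sizes give boundary percentiles", {
  sc <- sig_cohort()
  res <- random_signature_null(sc$genes[1:5], sc$expr, sc$surv, R = 1L,
                               seed = 9L)
  expect_true(res$percentile %in% c(0, 100))
})

test_that("cluster signature refinement recovers defining genes", {
  # 40 genes define cluster 1 against the rest at ~2 SD
  withr::with_seed(17, {
    n <- 90
    asg <- rep(1:3, each = 30)
    expr <- matrix(rnorm(500 * n), 500, n,
                   dimnames = list(sprintf("g%03d", 1:500), sprintf("s%03d", 1:n)))
    expr[1:40, asg == 1] <- expr[1:40, asg == 1] + 2
    cn <- matrix(2, 500, n, dimnames = dimnames(expr))
    model <- list(assignments = setNames(asg, colnames(expr)), K = 3L)
    top <- refine_cluster_signature(model, 1L, list(expr = expr, cn = cn),
                                    target_size = 50L)
    expect_gte(sum(sprintf("g%03d", 1:40) %in% top), 36L)
    # all genes requested returns the full ranking
    all_g <- refine_cluster_signature(model, 1L, list(expr = expr, cn = cn),
                                      target_size = 500L)
    expect_length(all_g, 500L)
    expect_error(refine_cluster_signature(model, 9L, list(expr = expr)),
                 "no samples")
    # indistinct clusters warn
    model2 <- list(assignments = setNames(rep(1:2, n / 2), colnames(expr)),
                   K = 2L)
    expect_warning(refine_cluster_signature(model2, 1L, list(cn = cn)),
                   "near-zero")
  })
})

test_that("the signature comparison table is stable and ranks planted signal", {
  sc <- sig_cohort()
  withr::with_seed(19, {
    sets <- list(planted = sc$genes,
                 planted_copy = sc$genes,
                 noise1 = sample(rownames(sc$expr)[51:1000], 50),
                 noise2 = sample(rownames(sc$expr)[51:1000], 50))
  })
  tab <- signature_comparison_table(sets, sc$expr, sc$surv, seed = 3L)
  expect_equal(tab$chi_square[1], tab$chi_square[2])
  expect_equal(tab$signature[which.min(tab$p_value)], "planted")
  expect_equal(nrow(signature_comparison_table(list(), sc$expr, sc$surv)), 0L)
  expect_warning(
    bad <- signature_comparison_table(list(absent = c("x", "y", "z")),
                                      sc$expr, sc$surv),
    "could not be scored"
  )
  expect_true(is.na(bad$chi_square))
})
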