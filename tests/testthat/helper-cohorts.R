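# shared fixtures (built in code) and independent oracles

# small default cohort reused across tests; built once per test run
.test_cohort_cache <- new.env(parent = emptyenv())

test_cohort <- function(seed = 101L, ...) {
  key <- paste0("c", seed, "_", paste(deparse(substitute(list(...))), collapse = ""))
  if (!is.null(.test_cohort_cache[[key]])) return(.test_cohort_cache[[key]])
  coh <- generate_cohort(sim_config(
    n_tumour = 150L, n_benign = 30L, n_genes = 1200L, seed = seed, ...
  ))
  .test_cohort_cache[[key]] <- coh
  coh
}

tumour_ids <- function(coh) coh$clinical$sample[coh$clinical$tissue == "tumour"]

truth_vec <- function(coh) {
  setNames(coh$truth$subtype_of_sample$subtype, coh$truth$subtype_of_sample$sample)
}

# run generator -> CN gene states -> probe collapse -> eQTL selection;
# returns the blocks that feed the integrative model
pipeline_blocks <- function(coh, n_features = 100L) {
  tum <- tumour_ids(coh)
  cn <- segments_to_gene_states(coh$segments, coh$annotation, samples = tum)
  eg <- suppressMessages(collapse_probes(coh$expression))
  feats <- cis_correlations(cn, eg, samples = tum)
  sel <- select_features(feats, min(n_features, nrow(feats)))
  list(blocks = list(expr = eg[sel, tum, drop = FALSE],
                     cn = cn[sel, tum, drop = FALSE] * 1.0),
       cn = cn, expr_gene = eg, feats = feats, selected = sel, tumour = tum)
}

# ---- independent oracles ----------------------------------------------------

# logrank by direct enumeration of event times: observed vs hypergeometric
# expectation, quadratic form with the standard variance estimate
logrank_oracle <- function(time, event, group) {
  group <- factor(group)
  G <- nlevels(group)
  times <- sort(unique(time[event == 1]))
  O <- E <- rep(0, G)
  V <- matrix(0, G, G)
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(event == 1 & time == t)
    for (g in seq_len(G)) {
      ng <- sum(at_risk & group == levels(group)[g])
      dg <- sum(event == 1 & time == t & group == levels(group)[g])
      O[g] <- O[g] + dg
      E[g] <- E[g] + d * ng / n
    }
    if (n > 1) {
      for (g in seq_len(G)) for (h in seq_len(G)) {
        ng <- sum(at_risk & group == levels(group)[g])
        nh <- sum(at_risk & group == levels(group)[h])
        V[g, h] <- V[g, h] +
          d * (n - d) / (n - 1) * (ng / n) * ((g == h) - nh / n)
      }
    }
  }
  u <- (O - E)[-1]
  chisq <- as.numeric(t(u) %*% solve(V[-1, -1, drop = FALSE]) %*% u)
  list(chi_square = chisq, df = G - 1)
}

# Adjusted Rand Index by exhaustive enumeration of all sample pairs
ari_oracle <- function(a, b) {
  n <- length(a)
  pairs <- utils::combn(n, 2)
  same_a <- apply(pairs, 2, function(ij) a[ij[1]] == a[ij[2]])
  same_b <- apply(pairs, 2, function(ij) b[ij[1]] == b[ij[2]])
  n11 <- sum(same_a & same_b); n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b); n01 <- sum(!same_a & same_b)
  np <- ncol(pairs)
  expected <- (n11 + n10) * (n11 + n01) / np
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  (n11 - expected) / (maxi - expected)
}

# Kaplan-Meier product-limit by hand
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_i <- sum(time >= ts[i])
    d_i <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    out[i] <- s
  }
  tibble::tibble(time = ts, surv = out)
}

# principal angle (radians) between column spans of A and B
principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  sv <- svd(crossprod(qa, qb))$d
  acos(min(1, min(sv)))
}
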