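#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n desc across pull distinct rename count
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_int map2 imap pmap list_rbind
#' @importFrom stats IQR cor kmeans kruskal.test median p.adjust pchisq pf pt
#'   qnorm quantile rbinom rexp rnorm runif sd setNames var rlnorm
#' @importFrom utils head
NULL

# soft-threshold operator used by the lasso M-step
soft_threshold <- function(x, lambda) {
  sign(x) * pmax(abs(x) - lambda, 0)
}

# interquartile range with linear interpolation between order statistics
# (quantile type 7); IQR of {1,2,3,4} is 1.5 under this rule
row_iqr <- function(m) {
  apply(m, 1L, IQR, type = 7)
}

stopifnot_matrix <- function(m, arg = "m") {
  if (!is.matrix(m) || !is.numeric(m)) {
    abort(sprintf("`%s` must be a numeric matrix (features x samples)", arg))
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort(sprintf("`%s` must have feature rownames and sample colnames", arg))
  }
  invisible(m)
}

# standardize matrix rows to mean 0, sd 1; constant rows become 0
standardize_rows <- function(m, center = NULL, scale = NULL) {
  if (is.null(center)) center <- rowMeans(m)
  if (is.null(scale)) {
    scale <- apply(m, 1L, sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  out <- (m - center) / scale
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

# derive a reproducible child seed from a root seed and a stream label;
# kept below 2^31 so it is always a valid R integer seed
child_seed <- function(seed, stream) {
  stream_num <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + stream_num) %% 2147483587) + 1L
}
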