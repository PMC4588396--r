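#' Collapse copy-number segments to per-gene integer states
#'
#' Each gene takes the CN state of the segment covering the majority of its
#' length, after discarding low-confidence calls (`rank > max_rank`). Genes
#' with no retained covering segment default to the diploid state 2 and are
#' flagged. An exact 50/50 overlap tie resolves to the state closer to
#' diploid.
#'
#' @param segments Segment tibble (`sample`, `chrom`, `start`, `end`, `cn`,
#'   `rank`; 0-based half-open).
#' @param annotation Gene annotation tibble (see [read_bed()]).
#' @param samples Optional sample ids to include (default: all in
#'   `segments`). Samples with no segments at all come out diploid.
#' @param max_rank Keep only calls with rank <= `max_rank` (confidence
#'   ranks run 1 = highest to 5).
#' @return Integer gene x sample matrix with attribute `flagged`, a tibble
#'   of (gene_id, sample) pairs defaulted to diploid for lack of coverage.
#' @export
segments_to_gene_states <- function(segments, annotation, samples = NULL,
                                    max_rank = 2L) {
  validate_segments(segments)
  samples <- samples %||% sort(unique(segments$sample))
  genes <- GenomicRanges::GRanges(
    annotation$chrom,
    IRanges::IRanges(annotation$start + 1, annotation$end)
  )
  gene_len <- annotation$end - annotation$start
  m <- matrix(2L, nrow = nrow(annotation), ncol = length(samples),
              dimnames = list(annotation$gene_id, samples))
  covered <- matrix(FALSE, nrow = nrow(annotation), ncol = length(samples),
                    dimnames = dimnames(m))

  segs <- segments |> filter(.data$rank <= max_rank, .data$sample %in% samples)
  if (nrow(segs)) {
    sgr <- GenomicRanges::GRanges(
      segs$chrom, IRanges::IRanges(segs$start + 1, segs$end)
    )
    # segments may legitimately cover no chromosome a gene sits on
    hits <- suppressWarnings(GenomicRanges::findOverlaps(genes, sgr))
    if (length(hits)) {
      gi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      ov <- IRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(genes)[gi], GenomicRanges::ranges(sgr)[si]
      ))
      cov <- tibble(
        gene = gi, sample = segs$sample[si], cn = segs$cn[si],
        frac = ov / gene_len[gi]
      ) |>
        group_by(.data$gene, .data$sample, .data$cn) |>
        summarise(frac = sum(.data$frac), .groups = "drop") |>
        group_by(.data$gene, .data$sample) |>
        # majority rule; at an exact tie the state closer to diploid wins
        arrange(desc(.data$frac), abs(.data$cn - 2L), .by_group = TRUE) |>
        dplyr::slice(1L) |>
        ungroup() |>
        filter(.data$frac > 0.5 - 1e-12)
      idx <- cbind(cov$gene, match(cov$sample, samples))
      m[idx] <- as.integer(cov$cn)
      covered[idx] <- TRUE
    }
  }
  flg <- which(!covered, arr.ind = TRUE)
  attr(m, "flagged") <- tibble(
    gene_id = rownames(m)[flg[, 1L]],
    sample = colnames(m)[flg[, 2L]]
  )
  attr(m, "max_rank") <- max_rank
  m
}

#' Per-gene recurrence of copy-number alteration across a cohort
#'
#' @param cn_matrix Integer gene x sample matrix from
#'   [segments_to_gene_states()].
#' @return Tibble with `gene_id`, `fraction_gain` (share of samples with
#'   state > 2) and `fraction_loss` (state < 2).
#' @export
cn_recurrence <- function(cn_matrix) {
  stopifnot_matrix(cn_matrix, "cn_matrix")
  tibble(
    gene_id = rownames(cn_matrix),
    fraction_gain = unname(rowMeans(cn_matrix > 2L)),
    fraction_loss = unname(rowMeans(cn_matrix < 2L))
  )
}

#' Keep genes altered in at least a minimum fraction of the cohort
#'
#' The boundary is inclusive ("at least"): a gene altered in exactly
#' `min_frac` of samples is retained.
#'
#' @param recurrence Tibble from [cn_recurrence()].
#' @param min_frac Minimum altered fraction (default 0.10).
#' @param per_direction If `TRUE`, gains and losses are tested separately
#'   (either direction alone must reach `min_frac`); default combines them.
#' @return Character vector of retained gene ids.
#' @export
filter_recurrent <- function(recurrence, min_frac = 0.10,
                             per_direction = FALSE) {
  keep <- if (per_direction) {
    recurrence$fraction_gain >= min_frac | recurrence$fraction_loss >= min_frac
  } else {
    recurrence$fraction_gain + recurrence$fraction_loss >= min_frac
  }
  recurrence$gene_id[keep]
}

#' Percent genome altered for one sample
#'
#' Sums the bases of non-diploid segments at or above the confidence cutoff
#' and divides by the conventional 3e9-base genome size.
#'
#' @param segments Segment tibble for a single sample.
#' @param max_rank Only calls with rank <= `max_rank` count (default 1,
#'   highest confidence only).
#' @param genome_size Denominator in bases (default 3e9).
#' @return Fraction in \[0, 1\].
#' @export
pga <- function(segments, max_rank = 1L, genome_size = 3e9) {
  if (nrow(segments) && length(unique(segments$sample)) > 1L) {
    abort("pga() expects segments of a single sample; see pga_all()")
  }
  altered <- segments |> filter(.data$cn != 2L, .data$rank <= max_rank)
  sum(altered$end - altered$start) / genome_size
}

#' Percent genome altered for every sample in a cohort
#'
#' @param segments Segment tibble (many samples).
#' @param samples Sample ids to report (default: those present in
#'   `segments`); samples without segments get PGA 0.
#' @inheritParams pga
#' @return Tibble with `sample` and `pga`.
#' @export
pga_all <- function(segments, samples = NULL, max_rank = 1L,
                    genome_size = 3e9) {
  samples <- samples %||% sort(unique(segments$sample))
  altered <- segments |>
    filter(.data$cn != 2L, .data$rank <= max_rank,
           .data$sample %in% samples) |>
    group_by(.data$sample) |>
    summarise(pga = sum(.data$end - .data$start) / genome_size)
  tibble(sample = samples) |>
    left_join(altered, by = "sample") |>
    mutate(pga = dplyr::coalesce(.data$pga, 0))
}

#' Compare percent genome altered between groups (Kruskal-Wallis)
#'
#' Rank-based K-group test with tie correction; the p-value comes from the
#' chi-square approximation with (groups - 1) degrees of freedom.
#'
#' @param values Numeric vector (e.g. per-sample PGA).
#' @param groups Group labels, same length.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
pga_by_group <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) abort("need >= 2 groups")
  if (length(values) != length(groups)) abort("values and groups must align")
  if (length(unique(values)) == 1L) {
    return(tibble(statistic = 0, df = nlevels(groups) - 1L, p_value = 1))
  }
  kt <- kruskal.test(values, groups)
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value)
}
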